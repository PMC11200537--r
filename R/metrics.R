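#' Dice coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|) * 100`, a percentage from 0 (complete mismatch)
#' to 100 (perfect match). Two empty masks score 100 (perfect agreement on
#' absence).
#'
#' @param A,B logical/0-1 arrays of identical shape.
#' @return percentage in `[0, 100]`.
#' @export
dice_coefficient <- function(A, B) {
  if (!identical(dim(A), dim(B)))
    stop("masks must have identical shapes", call. = FALSE)
  a <- A != 0
  b <- B != 0
  na <- sum(a)
  nb <- sum(b)
  if (na == 0 && nb == 0) return(100)
  200 * sum(a & b) / (na + nb)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' For each voxel of one mask, the Euclidean distance (in physical mm, via
#' the voxel spacing) to the nearest voxel of the other mask is computed
#' with an exact distance transform; the 95th percentile (linear
#' interpolation between order statistics) of each directed set is taken and
#' the two directions are symmetrised by their maximum. Computed over the
#' full voxel sets of the masks. If either mask is empty the distance is
#' undefined and `NA` is returned.
#'
#' @param A,B logical/0-1 arrays of identical shape.
#' @param spacing positive voxel spacing in mm (length 3).
#' @param probs percentile (default 0.95).
#' @return distance in mm, or `NA_real_` if undefined.
#' @export
hd95 <- function(A, B, spacing = c(1, 1, 1), probs = 0.95) {
  if (!identical(dim(A), dim(B)))
    stop("masks must have identical shapes", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  a <- array(as.integer(A != 0), dim(A))
  b <- array(as.integer(B != 0), dim(B))
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  d <- dim(a)
  dtb <- cpp_edt_sq(b, d, as.numeric(spacing))
  dta <- cpp_edt_sq(a, d, as.numeric(spacing))
  h_ab <- quantile(sqrt(dtb[a == 1L]), probs, names = FALSE, type = 7)
  h_ba <- quantile(sqrt(dta[b == 1L]), probs, names = FALSE, type = 7)
  max(h_ab, h_ba)
}

#' Per-class segmentation report
#'
#' Dice (percent) and HD95 (mm) for CSF, gray matter and white matter, plus
#' macro averages. Classes whose HD95 is undefined (an empty mask) are
#' excluded from the macro HD95 average, with the count noted.
#'
#' @param pred,gt `msca_labels` (or integer arrays) of identical shape.
#' @param spacing voxel spacing in mm; taken from `pred` if it is a
#'   `msca_labels` and not supplied.
#' @return data.frame with rows csf/gm/wm/macro and columns `class`,
#'   `dice_pct`, `hd95_mm`; attribute `hd95_defined` counts defined classes.
#' @export
evaluate_segmentation <- function(pred, gt, spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(pred, "msca_labels")) pred$spacing else c(1, 1, 1)
  p <- .as_label_array(pred)
  g <- .as_label_array(gt)
  if (!identical(dim(p), dim(g)))
    stop("pred and gt must have identical shapes", call. = FALSE)
  cls <- c(csf = 1L, gm = 2L, wm = 3L)
  rows <- lapply(names(cls), function(nm) {
    k <- cls[[nm]]
    data.frame(class = nm,
               dice_pct = dice_coefficient(p == k, g == k),
               hd95_mm = hd95(p == k, g == k, spacing))
  })
  df <- do.call(rbind, rows)
  defined <- !is.na(df$hd95_mm)
  macro <- data.frame(class = "macro", dice_pct = mean(df$dice_pct),
                      hd95_mm = if (any(defined)) mean(df$hd95_mm[defined])
                                else NA_real_)
  out <- rbind(df, macro)
  attr(out, "hd95_defined") <- sum(defined)
  out
}

#' Paired t-test with Bonferroni correction
#'
#' Two-sided paired t-test on per-case score differences, with the raw
#' p-value multiplied by the number of simultaneous comparisons (capped at
#' 1).
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2) of
#'   per-case scores for the two methods.
#' @param n_comparisons number of simultaneous comparisons (>= 1).
#' @return list with `t`, `p_raw`, `p_adjusted`, `degenerate` (TRUE when the
#'   differences have zero variance).
#' @export
paired_test_bonferroni <- function(scores_a, scores_b, n_comparisons = 1L) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  if (length(scores_a) < 2L) stop("need at least 2 paired cases", call. = FALSE)
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1", call. = FALSE)
  d <- scores_a - scores_b
  # treat numerically-constant differences as degenerate too: t.test errors
  # on "essentially constant" data
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-10)
      return(list(t = 0, p_raw = 1, p_adjusted = 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p_raw = 0, p_adjusted = 0,
                degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p_raw = tt$p.value,
       p_adjusted = min(1, n_comparisons * tt$p.value), degenerate = FALSE)
}
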