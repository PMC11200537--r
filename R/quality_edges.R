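#' Canny edge-detector parameters
#'
#' The detector runs slice-wise along the axial (third) axis: Gaussian
#' smoothing, Sobel gradients, non-maximum suppression along the quantised
#' gradient direction, then double-threshold hysteresis. Thresholds are
#' fractions of each slice's maximum gradient magnitude, which makes the
#' edge maps invariant to affine intensity rescaling of the input.
#'
#' @param sigma Gaussian smoothing scale in voxels (> 0).
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   slice-maximum gradient magnitude, `0 < low_frac < high_frac <= 1`.
#' @return a `canny_params` list.
#' @export
canny_params <- function(sigma = 1.0, low_frac = 0.1, high_frac = 0.2) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1))
    stop("need 0 < low_frac < high_frac <= 1", call. = FALSE)
  structure(list(sigma = sigma, low_frac = low_frac, high_frac = high_frac),
            class = "canny_params")
}

#' Slice-wise Canny edges of a 3D patch
#'
#' @param patch 3D numeric array (or `msca_volume`).
#' @param params a [canny_params()].
#' @return binary integer 3D array (1 = edge voxel); a constant patch yields
#'   an all-zero map.
#' @export
canny_edges <- function(patch, params = canny_params()) {
  x <- if (inherits(patch, "msca_volume")) patch$data else patch
  d <- dim(x)
  if (length(d) != 3L) stop("patch must be a 3D array", call. = FALSE)
  if (any(d[1:2] < 3L))
    stop("in-plane slice dimensions must be >= 3 voxels", call. = FALSE)
  array(cpp_canny_slices(as.double(x), d, params$sigma,
                         params$low_frac, params$high_frac), d)
}

#' Canny edges of a label patch
#'
#' Casts the integer class indices to a scalar image and applies
#' [canny_edges()]; a uniform label patch yields an empty map.
#'
#' @param label_patch 3D integer array (or `msca_labels`) with values 0..3.
#' @param params a [canny_params()].
#' @return binary integer 3D array.
#' @export
edges_of_labels <- function(label_patch, params = canny_params()) {
  x <- if (inherits(label_patch, "msca_labels")) label_patch$data else label_patch
  if (any(x < 0 | x > 3)) stop("label values must lie in {0..3}", call. = FALSE)
  canny_edges(array(as.double(x), dim(x)), params)
}

#' Edge-overlap label-quality weight
#'
#' Dice overlap between the edge map of an intensity patch and the edge map
#' of its label patch: `2 |EI & EL| / (|EI| + |EL|)`. A high overlap marks a
#' patch whose annotation agrees with the image structure. When both maps
#' are empty the weight is 1 (a background-only patch carries no evidence of
#' label error); when exactly one is empty it is 0.
#'
#' @param EI,EL binary 3D arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
quality_weight <- function(EI, EL) {
  if (!identical(dim(EI), dim(EL)))
    stop("edge maps must have identical shapes", call. = FALSE)
  nI <- sum(EI != 0)
  nL <- sum(EL != 0)
  if (nI == 0 && nL == 0) return(1)
  if (nI == 0 || nL == 0) return(0)
  2 * sum(EI != 0 & EL != 0) / (nI + nL)
}

#' Patchwise label-quality scores over a volume
#'
#' Tiles the volume with non-overlapping patches and reports the quality
#' weight of each, as used at training batch-assembly time.
#'
#' @param vol a `msca_volume`.
#' @param labels the paired `msca_labels`.
#' @param patch_size patch extent per axis.
#' @param params a [canny_params()].
#' @return data.frame with 0-based patch origins and `w_data`.
#' @export
qc_score_volume <- function(vol, labels, patch_size, params = canny_params()) {
  d <- dim(vol$data)
  size <- rep_len(as.integer(patch_size), 3L)
  starts <- lapply(1:3, function(a) seq(0L, d[a] - size[a], by = size[a]))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  grid$w_data <- vapply(seq_len(nrow(grid)), function(r) {
    o <- as.integer(grid[r, 1:3])
    ix <- lapply(1:3, function(a) (o[a] + 1L):(o[a] + size[a]))
    ip <- vol$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    lp <- labels$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    quality_weight(canny_edges(ip, params), edges_of_labels(lp, params))
  }, numeric(1))
  grid
}
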