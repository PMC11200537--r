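#' Loss configuration
#'
#' @param ds_weights deep-supervision weights, one per supervision head,
#'   ascending with resolution. Default `c(0.03125, 0.0625, 0.125, 0.25,
#'   0.5)` for the five decoder heads.
#' @param lambda_ trade-off weight of the data-quality term in the total
#'   loss (default 1; 0 disables it, the loss-ablation setting).
#' @param exclude_background if `TRUE` (default) the Dice term averages over
#'   the tissue classes CSF/GM/WM only, leaving the background channel out
#'   of the overlap average. The cross-entropy always averages over all
#'   voxels: background voxels must carry a supervised target, otherwise the
#'   network can never learn to emit the background class on uniform
#'   regions.
#' @param epsilon numerical floor for Dice denominators and log clamping.
#' @return a `loss_config` list.
#' @export
loss_config <- function(ds_weights = c(0.03125, 0.0625, 0.125, 0.25, 0.5),
                        lambda_ = 1, exclude_background = TRUE,
                        epsilon = 1e-5) {
  if (any(ds_weights <= 0)) stop("all ds_weights must be > 0", call. = FALSE)
  if (lambda_ < 0) stop("lambda_ must be >= 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(ds_weights = ds_weights, lambda_ = lambda_,
                 exclude_background = isTRUE(exclude_background),
                 epsilon = epsilon), class = "loss_config")
}

.as_label_array <- function(G) {
  if (inherits(G, "msca_labels")) G$data else G
}

.class_set <- function(cfg) if (cfg$exclude_background) 1:3 else 0:3

#' Soft Dice loss
#'
#' `1 - (1/|S|) sum_k 2 sum(P_k G_k) / (sum(P_k^2) + sum(G_k^2) + eps)` over
#' the classes in `class_set`.
#'
#' @param P probability array `(K, ...)`.
#' @param G one-hot array of the same shape.
#' @param class_set class codes averaged over (default tissue classes 1:3).
#' @param epsilon denominator floor.
#' @return scalar in `[0, 1]` (up to a small epsilon-induced excess).
#' @export
dice_loss <- function(P, G, class_set = 1:3, epsilon = 1e-5) {
  if (!identical(dim(P), dim(G)))
    stop("P and G must have identical shapes", call. = FALSE)
  if (length(class_set) == 0) stop("class_set must be non-empty", call. = FALSE)
  K <- dim(P)[1]
  pm <- matrix(P, K)
  gm <- matrix(G, K)
  terms <- vapply(class_set, function(k) {
    pk <- pm[k + 1L, ]
    gk <- gm[k + 1L, ]
    2 * sum(pk * gk) / (sum(pk * pk) + sum(gk * gk) + epsilon)
  }, numeric(1))
  1 - mean(terms)
}

.dice_loss_grad <- function(pm, lab, class_set, epsilon) {
  # pm: K x N prob matrix, lab: integer labels vector (0-based)
  K <- nrow(pm)
  dP <- matrix(0, K, ncol(pm))
  val <- 0
  for (k in class_set) {
    pk <- pm[k + 1L, ]
    gk <- as.numeric(lab == k)
    num <- 2 * sum(pk * gk)
    den <- sum(pk * pk) + sum(gk) + epsilon
    val <- val + num / den
    dP[k + 1L, ] <- -(2 * gk * den - num * 2 * pk) / (den * den) / length(class_set)
  }
  list(value = 1 - val / length(class_set), dP = dP)
}

#' Multi-class cross-entropy loss
#'
#' Mean over all voxels of `-log P_G(i)(i)` with probabilities clamped to
#' `[epsilon, 1]`. Every voxel enters the mean, including background ones:
#' the background class is a supervised target like any tissue class.
#'
#' @param P probability array `(K, ...)`.
#' @param G `msca_labels` or integer array matching `P`'s spatial shape.
#' @param cfg a [loss_config()].
#' @return scalar `>= 0`.
#' @export
cross_entropy_loss <- function(P, G, cfg = loss_config()) {
  lab <- .as_label_array(G)
  K <- dim(P)[1]
  if (!identical(dim(P)[-1], dim(lab)))
    stop("P spatial shape must match G", call. = FALSE)
  pm <- matrix(P, K)
  labv <- as.integer(lab)
  pg <- pm[(seq_along(labv) - 1L) * K + labv + 1L]
  mean(-log(pmax(pg, cfg$epsilon)))
}

.ce_loss_grad <- function(pm, labv, cfg) {
  K <- nrow(pm)
  dP <- matrix(0, K, ncol(pm))
  idx <- (seq_along(labv) - 1L) * K + labv + 1L
  pg <- pm[idx]
  n <- length(labv)
  val <- mean(-log(pmax(pg, cfg$epsilon)))
  live <- pg > cfg$epsilon
  dP[idx[live]] <- -1 / (pg[live] * n)
  list(value = val, dP = dP)
}

# upsample a (K, ...) probability array to the target spatial dims and
# renormalise per voxel; returns the renormalised probs plus what the
# gradient chain needs
.upsample_renorm <- function(P, target) {
  d <- dim(P)
  if (identical(d[-1], target)) return(list(r = P, native = TRUE))
  u <- cpp_resize_trilinear_fw(as.double(P), d, as.integer(target))
  u <- ftensor(u, c(d[1], target))
  um <- matrix(u, d[1])
  S <- .colSums(um, d[1], ncol(um))
  r <- sweep(um, 2, S, "/")
  list(r = ftensor(r, c(d[1], target)), native = FALSE, S = S, rm = r,
       idims = d)
}

.upsample_renorm_bw <- function(dR, up) {
  if (up$native) return(dR)
  K <- nrow(up$rm)
  dRm <- matrix(dR, K)
  # r = u / S with S the per-voxel channel sum:
  # dL/du_j = (dR_j - sum_k dR_k r_k) / S
  inner <- .colSums(dRm * up$rm, K, ncol(dRm))
  dU <- sweep(sweep(dRm, 2, inner, "-"), 2, up$S, "/")
  ftensor(cpp_resize_trilinear_bw(as.double(dU), c(K, dim(dR)[-1]), up$idims),
          up$idims)
}

#' Deep-supervised segmentation loss
#'
#' Each stage prediction is trilinearly upsampled to the ground-truth
#' resolution, renormalised per voxel, scored with Dice plus cross-entropy,
#' and the per-stage sums are combined with the deep-supervision weights:
#' `sum_s w_s (l_dice(P_s, G) + l_ce(P_s, G))`.
#'
#' @param stages a [forward_pass()] result, or a plain list of probability
#'   arrays ordered by ascending resolution (last at full resolution).
#' @param G `msca_labels` or integer label array at full resolution.
#' @param cfg a [loss_config()]; `length(ds_weights)` must equal the number
#'   of stages.
#' @return scalar loss.
#' @export
segmentation_loss <- function(stages, G, cfg = loss_config()) {
  outs <- if (is.list(stages) && !is.null(stages$outputs)) stages$outputs else stages
  if (length(outs) != length(cfg$ds_weights))
    stop("number of stage outputs (", length(outs),
         ") does not match ds_weights (", length(cfg$ds_weights), ")",
         call. = FALSE)
  lab <- .as_label_array(G)
  cs <- .class_set(cfg)
  total <- 0
  for (s in seq_along(outs)) {
    up <- .upsample_renorm(outs[[s]], dim(lab))
    Gh <- one_hot_encode(lab, dim(outs[[s]])[1])
    total <- total + cfg$ds_weights[s] *
      (dice_loss(up$r, Gh, cs, cfg$epsilon) + cross_entropy_loss(up$r, lab, cfg))
  }
  total
}

#' Quality-weighted data loss
#'
#' The edge-overlap quality score times the cross-entropy of the
#' full-resolution prediction: low-quality (label-noisy) patches contribute
#' proportionally less.
#'
#' @param P full-resolution probability array.
#' @param G `msca_labels` or integer label array.
#' @param w_data scalar quality weight in `[0, 1]` from [quality_weight()].
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
data_quality_loss <- function(P, G, w_data, cfg = loss_config()) {
  if (w_data < 0 || w_data > 1)
    stop("w_data must lie in [0, 1]", call. = FALSE)
  w_data * cross_entropy_loss(P, G, cfg)
}

#' Total training loss
#'
#' `L_total = L_seg + lambda * L_data`, where the data term applies to the
#' final (full-resolution) head only.
#'
#' @inheritParams segmentation_loss
#' @param w_data scalar quality weight of the patch.
#' @return list with `total`, `l_seg`, `l_data`.
#' @export
total_loss <- function(stages, G, w_data, cfg = loss_config()) {
  outs <- if (is.list(stages) && !is.null(stages$outputs)) stages$outputs else stages
  l_seg <- segmentation_loss(outs, G, cfg)
  l_data <- data_quality_loss(outs[[length(outs)]], G, w_data, cfg)
  list(total = l_seg + cfg$lambda_ * l_data, l_seg = l_seg, l_data = l_data)
}

#' Total loss and its gradient with respect to the stage logits
#'
#' The analytic backward pass used by the trainer: softmax, trilinear
#' upsampling and per-voxel renormalisation are all differentiated exactly.
#'
#' @param logits list of stage logit arrays `(K, ...)`, ascending resolution.
#' @param G `msca_labels` or integer label array at full resolution.
#' @param w_data scalar quality weight.
#' @param cfg a [loss_config()].
#' @return list with `loss` (total/l_seg/l_data) and `dlogits` (same shapes
#'   as `logits`).
#' @export
total_loss_grad <- function(logits, G, w_data, cfg = loss_config()) {
  lab <- .as_label_array(G)
  labv <- as.integer(lab)
  cs <- .class_set(cfg)
  S <- length(logits)
  dlogits <- vector("list", S)
  l_seg <- 0
  l_data <- 0
  for (s in seq_len(S)) {
    K <- dim(logits[[s]])[1]
    p <- channel_softmax(logits[[s]])
    up <- .upsample_renorm(p, dim(lab))
    rm <- matrix(up$r, K)
    gd <- .dice_loss_grad(rm, labv, cs, cfg$epsilon)
    gc <- .ce_loss_grad(rm, labv, cfg)
    w <- cfg$ds_weights[s]
    l_seg <- l_seg + w * (gd$value + gc$value)
    dR <- w * (gd$dP + gc$dP)
    if (s == S && cfg$lambda_ > 0) {
      l_data <- w_data * gc$value
      dR <- dR + cfg$lambda_ * w_data * gc$dP
    }
    dR <- ftensor(dR, dim(up$r))
    dp <- .upsample_renorm_bw(dR, up)
    # softmax backward: dz = p * (dp - sum_k dp_k p_k)
    pmat <- matrix(p, K)
    dpm <- matrix(dp, K)
    inner <- .colSums(dpm * pmat, K, ncol(pmat))
    dz <- pmat * (dpm - matrix(inner, K, ncol(pmat), byrow = TRUE))
    dlogits[[s]] <- ftensor(dz, dim(logits[[s]]))
  }
  if (cfg$lambda_ == 0) l_data <- 0
  list(loss = list(total = l_seg + cfg$lambda_ * l_data, l_seg = l_seg,
                   l_data = l_data),
       dlogits = dlogits)
}
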