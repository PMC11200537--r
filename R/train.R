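#' Training configuration
#'
#' Defaults follow the reference training schedule: SGD with momentum 0.99
#' and weight decay 3e-5, initial learning rate 0.01 with poly decay of
#' power 0.9 stepped per epoch, 128-cubed patches, axial flip/rotation
#' augmentation and loss computation excluding background voxels. Desk-scale
#' runs shrink `patch_size`, `max_epoch` and `iters_per_epoch`.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param max_epoch number of epochs (reference schedule: 500).
#' @param iters_per_epoch optimisation steps per epoch (reference: 250).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param weight_decay L2 penalty applied to convolution weights.
#' @param patch_size per-axis patch extent, divisible by 32.
#' @param batch_size patches per optimisation step.
#' @param lambda_ data-quality loss weight (see [loss_config()]).
#' @param seed master seed for sampling, augmentation and initialisation.
#' @param augment character subset of `c("axial_flip", "rotation")`.
#' @param fg_bias foreground-centred patch sampling probability.
#' @param folds cross-validation fold count.
#' @param patience early-stopping patience in epochs on validation mean
#'   Dice (`Inf` disables).
#' @param canny a [canny_params()] for the patch quality scores.
#' @return a `train_config` list.
#' @export
train_config <- function(initial_lr = 0.01, max_epoch = 500L,
                         iters_per_epoch = 250L, momentum = 0.99,
                         weight_decay = 3e-5, patch_size = 128L,
                         batch_size = 2L, lambda_ = 1, seed = 1L,
                         augment = c("axial_flip", "rotation"),
                         fg_bias = 0.5, folds = 5L, patience = Inf,
                         canny = canny_params()) {
  if (initial_lr <= 0) stop("initial_lr must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)", call. = FALSE)
  patch_size <- rep_len(as.integer(patch_size), 3L)
  if (any(patch_size %% 32L != 0L))
    stop("patch_size must be divisible by 32", call. = FALSE)
  bad <- setdiff(augment, c("axial_flip", "rotation"))
  if (length(bad)) stop("unknown augmentation flag: ", bad[1], call. = FALSE)
  structure(list(initial_lr = initial_lr, max_epoch = as.integer(max_epoch),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 momentum = momentum, weight_decay = weight_decay,
                 patch_size = patch_size, batch_size = as.integer(batch_size),
                 lambda_ = lambda_, seed = as.integer(seed), augment = augment,
                 fg_bias = fg_bias, folds = as.integer(folds),
                 patience = patience, canny = canny),
            class = "train_config")
}

#' Poly learning-rate schedule
#'
#' `initial_lr * (1 - epoch_id / max_epoch)^0.9`, stepped per epoch.
#'
#' @param epoch_id 0-based epoch index in `[0, max_epoch]`.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
poly_lr <- function(epoch_id, cfg) {
  if (any(epoch_id < 0) || any(epoch_id > cfg$max_epoch))
    stop("epoch_id out of range [0, max_epoch]", call. = FALSE)
  cfg$initial_lr * (1 - epoch_id / cfg$max_epoch)^0.9
}

.flip_axis <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# right-angle rotation about the axial (third) axis, k in {1,2,3}
.rot_axial <- function(a, k) {
  for (i in seq_len(k)) a <- .flip_axis(aperm(a, c(2, 1, 3)), 1)
  a
}

.augment_rng <- function(pair, flags) {
  if ("axial_flip" %in% flags && runif(1) < 0.5) {
    ax <- sample(1:2, 1)
    pair$image <- .flip_axis(pair$image, ax)
    pair$labels <- .flip_axis(pair$labels, ax)
  }
  if ("rotation" %in% flags && runif(1) < 0.5) {
    k <- sample(1:3, 1)
    pair$image <- .rot_axial(pair$image, k)
    pair$labels <- .rot_axial(pair$labels, k)
  }
  pair
}

#' Augment an image/label patch pair
#'
#' With probability 0.5 each: a flip along one axial in-plane axis, and a
#' right-angle rotation about the axial axis. Image and labels are
#' transformed identically; deterministic under `seed`.
#'
#' @param pair list with `image` and `labels` 3D arrays (a [sample_patch()]
#'   result).
#' @param seed integer.
#' @param flags subset of `c("axial_flip", "rotation")`.
#' @return the (possibly) transformed pair.
#' @export
augment_patch <- function(pair, seed, flags = c("axial_flip", "rotation")) {
  bad <- setdiff(flags, c("axial_flip", "rotation"))
  if (length(bad)) stop("unknown augmentation flag: ", bad[1], call. = FALSE)
  if (length(flags) == 0) return(pair)
  with_seed(seed, .augment_rng(pair, flags))
}

#' K-fold cross-validation split
#'
#' Shuffles `0..n_items-1` under the seed and deals the indices into k
#' validation sets whose sizes differ by at most one.
#'
#' @param n_items number of cases (`>= k`).
#' @param k number of folds (`>= 2`).
#' @param seed integer.
#' @return list of `k` lists with 0-based `train` and `val` index vectors.
#' @export
kfold_split <- function(n_items, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n_items) stop("k must not exceed n_items", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_items)) - 1L
  fold_of <- rep_len(seq_len(k), n_items)
  lapply(seq_len(k), function(f) {
    val <- sort(perm[fold_of == f])
    list(train = sort(setdiff(perm, val)), val = val)
  })
}

# --- SGD ------------------------------------------------------------------

# momentum buffers mirroring the gradient structure
.zeros_like <- function(g) {
  if (is.numeric(g)) return(g * 0)
  lapply(g, .zeros_like)
}

# recursive SGD-with-momentum update driven by the gradient structure;
# weight decay applies to convolution kernels only, not to normalisation
# scales/shifts or biases; unnamed levels (stages, branches) recurse by
# position
.sgd_update_list <- function(params, grads, mom, lr, momentum, wd) {
  if (is.null(names(grads))) {
    for (i in seq_along(grads)) {
      res <- .sgd_update_list(params[[i]], grads[[i]], mom[[i]], lr, momentum, wd)
      params[[i]] <- res$params
      mom[[i]] <- res$mom
    }
    return(list(params = params, mom = mom))
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.numeric(g)) {
      gg <- g
      if (wd > 0 && nm %in% c("w", "dw", "pw", "wa", "wb", "wc"))
        gg <- gg + wd * params[[nm]]
      mom[[nm]] <- momentum * mom[[nm]] + gg
      params[[nm]] <- params[[nm]] - lr * mom[[nm]]
    } else {
      res <- .sgd_update_list(params[[nm]], g, mom[[nm]], lr, momentum, wd)
      params[[nm]] <- res$params
      mom[[nm]] <- res$mom
    }
  }
  list(params = params, mom = mom)
}

.accumulate_grads <- function(acc, g, scale = 1) {
  if (is.numeric(g)) {
    if (is.null(acc)) return(g * scale)
    return(acc + g * scale)
  }
  if (is.null(acc)) acc <- vector("list", length(g))
  names(acc) <- names(g)
  for (i in seq_along(g)) acc[[i]] <- .accumulate_grads(acc[[i]], g[[i]], scale)
  acc
}

# per-volume z-score statistics used to standardise network inputs
.zscore_stats <- function(vol) {
  m <- mean(vol$data)
  s <- sd(as.vector(vol$data))
  if (!is.finite(s) || s == 0) s <- 1
  c(mean = m, sd = s)
}

# --- training loop --------------------------------------------------------

#' Train a segmentation network
#'
#' Patch-based SGD training: each iteration samples `batch_size` patches
#' (foreground-biased), scores each patch's label quality from the edge
#' overlap of its raw (pre-augmentation) image and label patches, augments,
#' standardises intensities with the per-volume z-score (mean/sd over all
#' voxels of the case), runs forward/backward through all deep-supervision
#' heads, and applies an SGD-with-momentum step with the poly learning rate
#' of the current epoch. Quality scoring always sees the raw, un-normalised
#' patch. Fully reproducible under `cfg$seed` in single-threaded execution.
#'
#' @param data list of cases, each a list with `volume` (`msca_volume`) and
#'   `labels` (`msca_labels`) — e.g. [generate_phantom()] outputs.
#' @param cfg a [train_config()].
#' @param arch an [arch_config()].
#' @param val_data optional list of cases for per-epoch validation Dice
#'   (mean foreground Dice via [predict_volume()]); enables early stopping
#'   when `cfg$patience` is finite.
#' @param verbose print a line per epoch.
#' @return list with `net` (trained `msca_network`) and `log` (data.frame
#'   with per-iteration epoch, iteration, lr, l_seg, l_data, l_total,
#'   w_data_mean; per-epoch validation Dice in `attr(log, "val_dice")`).
#' @export
train_model <- function(data, cfg, arch, val_data = NULL, verbose = FALSE) {
  if (length(data) == 0) stop("training data is empty", call. = FALSE)
  stopifnot(inherits(cfg, "train_config"), inherits(arch, "arch_config"))
  net <- build_network(arch, seed = cfg$seed)
  zs <- lapply(data, function(case) .zscore_stats(case$volume))
  lcfg <- loss_config(lambda_ = cfg$lambda_)
  mom <- NULL
  nit <- cfg$max_epoch * cfg$iters_per_epoch
  log <- data.frame(epoch = integer(nit), iteration = integer(nit),
                    lr = numeric(nit), l_seg = numeric(nit),
                    l_data = numeric(nit), l_total = numeric(nit),
                    w_data_mean = numeric(nit))
  val_hist <- numeric(0)
  best_val <- -Inf
  since_best <- 0L
  row <- 0L

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epoch)) {
      lr <- poly_lr(epoch - 1L, cfg)
      for (it in seq_len(cfg$iters_per_epoch)) {
        acc <- NULL
        wsum <- 0
        lseg <- 0; ldata <- 0; ltot <- 0
        for (b in seq_len(cfg$batch_size)) {
          ci <- sample.int(length(data), 1L)
          case <- data[[ci]]
          pair <- .sample_patch_rng(case$volume, case$labels, cfg$patch_size,
                                    cfg$fg_bias)
          wd <- quality_weight(canny_edges(pair$image, cfg$canny),
                               edges_of_labels(pair$labels, cfg$canny))
          pair <- .augment_rng(pair, cfg$augment)
          img <- (pair$image - zs[[ci]]["mean"]) / zs[[ci]]["sd"]
          x <- ftensor(as.double(img), c(1L, dim(img)))
          fw <- net_forward(net, x, keep_cache = TRUE)
          lg <- total_loss_grad(fw$logits, pair$labels, wd, lcfg)
          g <- net_backward(net, fw$caches, lg$dlogits)
          acc <- .accumulate_grads(acc, g, 1 / cfg$batch_size)
          wsum <- wsum + wd
          lseg <- lseg + lg$loss$l_seg / cfg$batch_size
          ldata <- ldata + lg$loss$l_data / cfg$batch_size
          ltot <- ltot + lg$loss$total / cfg$batch_size
        }
        if (is.null(mom)) mom <- .zeros_like(acc)
        upd <- .sgd_update_list(net$params, acc, mom, lr, cfg$momentum,
                                cfg$weight_decay)
        net$params <- upd$params
        mom <- upd$mom
        row <- row + 1L
        log[row, ] <- list(epoch, it, lr, lseg, ldata, ltot,
                           wsum / cfg$batch_size)
      }
      if (!is.null(val_data)) {
        vd <- mean(vapply(val_data, function(case) {
          pred <- predict_volume(net, case$volume, cfg)
          mean(vapply(1:3, function(k)
            dice_coefficient(pred$data == k, case$labels$data == k) / 100,
            numeric(1)))
        }, numeric(1)))
        val_hist <- c(val_hist, vd)
        if (vd > best_val) { best_val <- vd; since_best <- 0L }
        else since_best <- since_best + 1L
        if (verbose) message(sprintf("epoch %d lr %.5f val dice %.4f",
                                     epoch, lr, vd))
        if (since_best >= cfg$patience) break
      } else if (verbose) {
        message(sprintf("epoch %d lr %.5f loss %.4f", epoch, lr, ltot))
      }
    }
  })
  log <- log[seq_len(row), ]
  attr(log, "val_dice") <- val_hist
  list(net = net, log = log)
}

# --- inference ------------------------------------------------------------

.gaussian_window <- function(size, sigma_frac = 1 / 8) {
  w <- lapply(1:3, function(a) {
    ctr <- (size[a] - 1) / 2
    exp(-0.5 * ((seq_len(size[a]) - 1 - ctr) / (sigma_frac * size[a]))^2)
  })
  out <- outer(outer(w[[1]], w[[2]]), w[[3]])
  array(out / max(out), size)
}

#' Whole-volume sliding-window inference
#'
#' Standardises the volume with its own z-score (the same per-volume
#' convention used in training), pads it to at least the patch size (and
#' window-step alignment), tiles it with 50 percent overlap, blends
#' per-window class probabilities with a Gaussian importance map, and takes
#' the channel argmax.
#'
#' @param net a trained `msca_network`.
#' @param vol a `msca_volume`.
#' @param cfg a [train_config()] (supplies `patch_size`).
#' @return a `msca_labels` prediction with the shape of `vol`.
#' @export
predict_volume <- function(net, vol, cfg) {
  if (!inherits(net, "msca_network"))
    stop("net must be a built/trained msca_network", call. = FALSE)
  size <- cfg$patch_size
  d0 <- dim(vol$data)
  step <- size %/% 2L
  dpad <- pmax(d0, size)
  dpad <- dpad + (step - (dpad - size) %% step) %% step
  zs <- .zscore_stats(vol)
  x <- array(0, dpad)
  x[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <-
    (vol$data - zs["mean"]) / zs["sd"]
  K <- net$cfg$n_classes
  probs <- array(0, c(K, dpad))
  wacc <- array(0, dpad)
  gw <- .gaussian_window(size)
  starts <- lapply(1:3, function(a) unique(c(seq(1L, dpad[a] - size[a] + 1L,
                                                 by = step[a]),
                                             dpad[a] - size[a] + 1L)))
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    ix <- list(sx:(sx + size[1] - 1L), sy:(sy + size[2] - 1L),
               sz:(sz + size[3] - 1L))
    patch <- x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    fp <- forward_pass(net, patch)
    p <- fp$outputs[[length(fp$outputs)]]
    for (k in seq_len(K))
      probs[k, ix[[1]], ix[[2]], ix[[3]]] <-
        probs[k, ix[[1]], ix[[2]], ix[[3]]] + p[k, , , ] * gw
    wacc[ix[[1]], ix[[2]], ix[[3]]] <- wacc[ix[[1]], ix[[2]], ix[[3]]] + gw
  }
  for (k in seq_len(K)) probs[k, , , ] <- probs[k, , , ] / wacc
  lab <- channel_argmax(probs)
  as_labelmap(lab[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE],
              vol$spacing, vol$affine)
}
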