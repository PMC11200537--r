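#' Synthetic brain phantom configuration
#'
#' Describes a skull-stripped, bias-corrupted T1-like phantom built from three
#' nested ellipsoidal shells sharing the volume centre: CSF between the outer
#' and middle shells, gray matter between middle and inner, white matter
#' inside the inner shell, background elsewhere. Intensities are per-class
#' Gaussian draws, optionally modulated by a smooth multiplicative
#' exponential-polynomial bias field and additive Gaussian or Rician noise.
#'
#' @param shape per-axis extent in voxels.
#' @param shell_radii list of three descending semi-axis sets (`outer`,
#'   `middle`, `inner`) expressed as fractions of `shape`.
#' @param class_means intensity means for (CSF, GM, WM), arbitrary units.
#' @param class_sds per-class intensity standard deviations.
#' @param bias_coeffs named coefficients of the log-bias polynomial (see
#'   [apply_bias_field()]); empty means no bias.
#' @param noise_sd additive noise standard deviation.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param spacing voxel spacing in mm.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(96, 96, 96),
                           shell_radii = list(outer = c(0.45, 0.45, 0.45),
                                              middle = c(0.35, 0.35, 0.35),
                                              inner = c(0.22, 0.22, 0.22)),
                           class_means = c(csf = 40, gm = 90, wm = 140),
                           class_sds = c(csf = 6, gm = 8, wm = 8),
                           bias_coeffs = numeric(0),
                           noise_sd = 4,
                           noise_model = c("gaussian", "rician"),
                           spacing = c(1, 1, 1)) {
  noise_model <- match.arg(noise_model)
  shape <- rep_len(as.integer(shape), 3L)
  r <- lapply(shell_radii, function(x) rep_len(as.numeric(x), 3L))
  if (!all(r$outer > r$middle) || !all(r$middle > r$inner))
    stop("shell radii must be strictly nested (outer > middle > inner on every axis)",
         call. = FALSE)
  if (any(class_sds < 0) || noise_sd < 0)
    stop("class_sds and noise_sd must be >= 0", call. = FALSE)
  structure(list(shape = shape, shell_radii = r,
                 class_means = class_means, class_sds = class_sds,
                 bias_coeffs = bias_coeffs, noise_sd = noise_sd,
                 noise_model = noise_model, spacing = as.numeric(spacing)),
            class = "phantom_config")
}

# normalised coordinates in [-1, 1] along one axis
.norm_coord <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1

# evaluate the log-bias polynomial given named monomial coefficients
# (names over the alphabet {x,y,z}, e.g. "" or "1" constant, "x", "xy", "xxz")
.eval_bias_poly <- function(coeffs, shape) {
  field <- array(0, shape)
  if (length(coeffs) == 0) return(field)
  cx <- .norm_coord(shape[1]); cy <- .norm_coord(shape[2]); cz <- .norm_coord(shape[3])
  X <- array(cx, shape)
  Y <- array(rep(cy, each = shape[1]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)
  nm <- names(coeffs)
  if (is.null(nm)) stop("bias_coeffs must be a named vector of monomials", call. = FALSE)
  for (i in seq_along(coeffs)) {
    term <- nm[i]
    if (term %in% c("", "1")) { field <- field + coeffs[i]; next }
    chars <- strsplit(term, "")[[1]]
    if (!all(chars %in% c("x", "y", "z")) || length(chars) > 3)
      stop("bias monomial '", term, "' not understood (order <= 3 over x,y,z)",
           call. = FALSE)
    mono <- array(1, shape)
    for (ch in chars) mono <- mono * switch(ch, x = X, y = Y, z = Z)
    field <- field + coeffs[i] * mono
  }
  field
}

#' Apply a multiplicative exponential-polynomial bias field
#'
#' Multiplies a volume by `exp(poly(v))` where `poly` is a polynomial of order
#' at most 3 over coordinates normalised to `[-1, 1]` per axis. The
#' exponential guarantees a strictly positive field, mimicking MRI shading.
#'
#' @param vol a `msca_volume`.
#' @param bias_coeffs named numeric vector; names are monomials over
#'   `{x, y, z}` (`"1"` or `""` for the constant), e.g.
#'   `c("1" = 0.1, x = 0.2, xz = -0.05)`.
#' @return the biased `msca_volume`.
#' @export
apply_bias_field <- function(vol, bias_coeffs) {
  field <- .eval_bias_poly(bias_coeffs, dim(vol$data))
  out <- vol
  out$data <- vol$data * exp(field)
  out
}

#' Generate a synthetic brain phantom
#'
#' @param cfg a [phantom_config()].
#' @param seed integer; the same seed reproduces the phantom bitwise.
#' @return list with `volume` (`msca_volume`) and `labels` (`msca_labels`).
#' @export
generate_phantom <- function(cfg, seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$shape
  ctr <- (d - 1) / 2
  ax <- lapply(1:3, function(a) seq_len(d[a]) - 1 - ctr[a])
  inside <- function(semi) {
    s <- semi * d
    q1 <- (ax[[1]] / s[1])^2
    q2 <- (ax[[2]] / s[2])^2
    q3 <- (ax[[3]] / s[3])^2
    array(outer(outer(q1, q2, "+"), q3, "+") <= 1, d)
  }
  lab <- array(0L, d)
  lab[inside(cfg$shell_radii$outer)] <- CLASS_CODES[["csf"]]
  lab[inside(cfg$shell_radii$middle)] <- CLASS_CODES[["gm"]]
  lab[inside(cfg$shell_radii$inner)] <- CLASS_CODES[["wm"]]

  means <- c(0, cfg$class_means)[lab + 1L]
  sds <- c(0, cfg$class_sds)[lab + 1L]
  img <- with_seed(seed, {
    base <- means + rnorm(length(lab)) * sds
    if (cfg$noise_model == "gaussian") {
      base + rnorm(length(lab), sd = cfg$noise_sd)
    } else {
      sqrt((base + rnorm(length(lab), sd = cfg$noise_sd))^2 +
             rnorm(length(lab), sd = cfg$noise_sd)^2)
    }
  })
  img <- array(img, d)
  if (length(cfg$bias_coeffs)) img <- img * exp(.eval_bias_poly(cfg$bias_coeffs, d))
  list(volume = as_volume(img, cfg$spacing),
       labels = as_labelmap(lab, cfg$spacing))
}

#' Label corruption specification
#'
#' @param mode one of `"erode"`, `"dilate"`, `"boundary_jitter"`,
#'   `"class_swap"`.
#' @param severity non-negative integer: structuring-element radius for the
#'   morphological modes, amplitude for the stochastic modes. Severity 0 is
#'   the identity for every mode.
#' @param target_class class code 1..3 or `"all"`.
#' @return a `corruption_spec` list.
#' @export
corruption_spec <- function(mode, severity, target_class = "all") {
  modes <- c("erode", "dilate", "boundary_jitter", "class_swap")
  if (!mode %in% modes)
    stop("unknown corruption mode '", mode, "'", call. = FALSE)
  if (severity < 0) stop("severity must be >= 0", call. = FALSE)
  structure(list(mode = mode, severity = as.integer(severity),
                 target_class = target_class), class = "corruption_spec")
}

# boundary voxels: any 6-neighbour with a different label (volume border
# neighbours ignored)
.boundary_mask <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  sh <- function(a, off) {
    i <- lapply(1:3, function(k) seq_len(d[k]))
    j <- i
    i[[a]] <- seq_len(d[a] - 1) + ifelse(off > 0, 0, 1)
    j[[a]] <- i[[a]] + off
    diffm <- lab[i[[1]], i[[2]], i[[3]], drop = FALSE] !=
      lab[j[[1]], j[[2]], j[[3]], drop = FALSE]
    bb <- array(FALSE, d)
    bb[i[[1]], i[[2]], i[[3]]] <- diffm
    bb
  }
  for (a in 1:3) for (off in c(-1L, 1L)) b <- b | sh(a, off)
  b
}

#' Corrupt a label map in a controlled way
#'
#' Emulates inaccurate annotations: morphological erosion/dilation of one
#' class, stochastic boundary jitter, or random within-foreground class
#' swaps. Severity 0 always returns the input unchanged.
#'
#' @param labels a `msca_labels`.
#' @param spec a [corruption_spec()].
#' @param seed integer for the stochastic modes; deterministic under seed.
#' @return the corrupted `msca_labels`.
#' @export
corrupt_labels <- function(labels, spec, seed = 1L) {
  stopifnot(inherits(spec, "corruption_spec"))
  if (spec$severity == 0L) return(labels)
  lab <- labels$data
  d <- dim(lab)
  targets <- if (identical(spec$target_class, "all")) 1:3 else as.integer(spec$target_class)

  if (spec$mode %in% c("erode", "dilate")) {
    for (tc in targets) {
      mask <- array(as.integer(lab == tc), d)
      res <- cpp_ball_morph(mask, d, spec$severity, spec$mode == "dilate")
      res <- array(res, d)
      if (spec$mode == "erode") {
        lab[mask == 1L & res == 0L] <- 0L   # shaved voxels fall to background
      } else {
        lab[res == 1L & mask == 0L] <- tc   # grown voxels overwrite neighbours
      }
    }
    return(as_labelmap(lab, labels$spacing, labels$affine))
  }

  with_seed(seed, {
    if (spec$mode == "boundary_jitter") {
      bnd <- .boundary_mask(labels$data)
      if (!identical(spec$target_class, "all"))
        bnd <- bnd & (labels$data %in% targets)
      idx <- which(bnd)
      p <- min(1, 0.25 * spec$severity)
      hit <- idx[runif(length(idx)) < p]
      if (length(hit)) {
        # relabel to a uniformly drawn 6-neighbouring class different from own
        nb_off <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
        co <- arrayInd(hit, d)
        for (r in seq_along(hit)) {
          own <- labels$data[hit[r]]
          cand <- integer(0)
          for (n in 1:6) {
            q <- co[r, ] + nb_off[n, ]
            if (all(q >= 1) && all(q <= d)) {
              v <- labels$data[q[1], q[2], q[3]]
              if (v != own) cand <- c(cand, v)
            }
          }
          if (length(cand)) lab[hit[r]] <- cand[sample.int(length(cand), 1L)]
        }
      }
    } else {  # class_swap
      p <- min(1, 0.05 * spec$severity)
      for (tc in targets) {
        idx <- which(labels$data == tc)
        hit <- idx[runif(length(idx)) < p]
        if (length(hit)) {
          others <- setdiff(1:3, tc)
          lab[hit] <- others[sample.int(2L, length(hit), replace = TRUE)]
        }
      }
    }
    as_labelmap(lab, labels$spacing, labels$affine)
  })
}
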