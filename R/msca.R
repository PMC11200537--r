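#' 3D multiscale convolutional attention parameters
#'
#' Configuration of one attention block: a depth-wise aggregation
#' convolution, parallel multiscale branches of three sequential depth-wise
#' strip convolutions (`k x 1 x 1`, `1 x k x 1`, `1 x 1 x k`, same padding),
#' an identity branch, and a pointwise (1x1x1) convolution whose output
#' reweighs the block input element-wise.
#'
#' @param channels feature channel count (>= 1).
#' @param dw_kernel extent of the depth-wise aggregation kernel (odd, >= 3).
#' @param branch_kernels strip kernel extents, default `c(5, 7, 11)`.
#' @param include_identity_branch keep the identity branch in the sum.
#' @return a `msca_params` list.
#' @export
msca_params <- function(channels, dw_kernel = 5L, branch_kernels = c(5L, 7L, 11L),
                        include_identity_branch = TRUE) {
  ks <- c(dw_kernel, branch_kernels)
  if (any(ks %% 2 == 0L) || any(ks < 3L))
    stop("all kernel extents must be odd and >= 3", call. = FALSE)
  if (channels < 1L) stop("channels must be >= 1", call. = FALSE)
  structure(list(channels = as.integer(channels), dw_kernel = as.integer(dw_kernel),
                 branch_kernels = as.integer(branch_kernels),
                 include_identity_branch = isTRUE(include_identity_branch)),
            class = "msca_params")
}

#' Initialise weights for an attention block
#'
#' Draws He-initialised weights from the ambient RNG (seed it with
#' [set.seed()] or via [build_network()] for reproducibility).
#'
#' @param params a [msca_params()].
#' @return named list of weight arrays (`dw`, per-branch strip kernels,
#'   pointwise `pw`/`pwb`).
#' @export
msca_init <- function(params) {
  C <- params$channels
  kd <- params$dw_kernel
  br <- lapply(params$branch_kernels, function(k) list(
    wa = init_dw_w(C, c(k, 1L, 1L)),
    wb = init_dw_w(C, c(1L, k, 1L)),
    wc = init_dw_w(C, c(1L, 1L, k))))
  list(dw = init_dw_w(C, rep(kd, 3L)),
       branches = br,
       pw = matrix(rnorm(C * C, sd = sqrt(2 / C)), C, C),
       pwb = numeric(C),
       params = params)
}

msca_fw <- function(x, wts) {
  p <- wts$params
  stopifnot_shape(dim(x)[1] == p$channels,
                  sprintf("msca_block: input has %d channels, expected %d",
                          dim(x)[1], p$channels))
  kd <- rep(p$dw_kernel, 3L)
  a0 <- dwconv_fw(x, wts$dw, kd)
  s <- if (p$include_identity_branch) a0$y else ftensor(numeric(length(a0$y)), dim(a0$y))
  bc <- vector("list", length(p$branch_kernels))
  for (i in seq_along(p$branch_kernels)) {
    k <- p$branch_kernels[i]
    b1 <- dwconv_fw(a0$y, wts$branches[[i]]$wa, c(k, 1L, 1L))
    b2 <- dwconv_fw(b1$y, wts$branches[[i]]$wb, c(1L, k, 1L))
    b3 <- dwconv_fw(b2$y, wts$branches[[i]]$wc, c(1L, 1L, k))
    s <- s + b3$y
    bc[[i]] <- list(b1 = b1$cache, b2 = b2$cache, b3 = b3$cache)
  }
  att <- pconv_fw(s, wts$pw, wts$pwb)
  y <- att$y * x
  list(y = y, cache = list(x = x, a0 = a0$cache, a0y = a0$y, bc = bc,
                           att = att$cache, atty = att$y))
}

msca_bw <- function(dy, wts, cache) {
  p <- wts$params
  datt <- dy * cache$x
  dx <- dy * cache$atty
  gp <- pconv_bw(datt, wts$pw, cache$att)
  ds <- gp$dx
  da0 <- if (p$include_identity_branch) ds else ftensor(numeric(length(ds)), dim(ds))
  gb <- vector("list", length(p$branch_kernels))
  for (i in seq_along(p$branch_kernels)) {
    g3 <- dwconv_bw(ds, wts$branches[[i]]$wc, cache$bc[[i]]$b3)
    g2 <- dwconv_bw(g3$dx, wts$branches[[i]]$wb, cache$bc[[i]]$b2)
    g1 <- dwconv_bw(g2$dx, wts$branches[[i]]$wa, cache$bc[[i]]$b1)
    da0 <- da0 + g1$dx
    gb[[i]] <- list(wa = g1$dw, wb = g2$dw, wc = g3$dw)
  }
  g0 <- dwconv_bw(da0, wts$dw, cache$a0)
  dx <- dx + g0$dx
  list(dx = dx, grads = list(dw = g0$dw, branches = gb, pw = gp$dw,
                             pwb = gp$db))
}

#' Apply a 3D multiscale convolutional attention block
#'
#' Computes `Conv1x1x1( sum_i Sca_i( ConvD(X) ) ) * X` where `ConvD` is the
#' depth-wise aggregation convolution, `Sca_0` the identity branch, each
#' `Sca_i` (i >= 1) three sequential depth-wise strip convolutions of extent
#' k along one axis each, and `*` an element-wise product with the block
#' input. The output shape equals the input shape.
#'
#' @param x channel-first feature array `(C, X, Y, Z)`.
#' @param weights a weight list from [msca_init()] (or hand-constructed with
#'   the same layout).
#' @return feature array of the same shape as `x`.
#' @export
msca_block <- function(x, weights) {
  msca_fw(x, weights)$y
}
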