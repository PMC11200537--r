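# Layer primitives with explicit forward/backward passes. Feature tensors
# are channel-first arrays (C, X, Y, Z); weights live in the matrix layouts
# expected by the compiled kernels (see src/kernels.cpp).

conv_fw <- function(x, w, b, k, stride = c(1L, 1L, 1L)) {
  d <- dim(x)
  pad <- as.integer(k %/% 2L)
  y <- cpp_conv3d_fw(as.double(x), d, w, b, as.integer(k), as.integer(stride), pad)
  od <- attr(y, "odims")
  list(y = ftensor(y, od), cache = list(x = x, k = as.integer(k),
                                        stride = as.integer(stride),
                                        pad = pad, ydims = od))
}

conv_bw <- function(dy, w, cache) {
  g <- cpp_conv3d_bw(as.double(cache$x), dim(cache$x), w, as.double(dy),
                     cache$ydims, cache$k, cache$stride, cache$pad)
  list(dx = ftensor(g$dx, dim(cache$x)), dw = g$dw, db = g$db)
}

deconv_fw <- function(x, w, b) {
  d <- dim(x)
  y <- cpp_deconv2_fw(as.double(x), d, w, b)
  od <- attr(y, "odims")
  list(y = ftensor(y, od), cache = list(x = x))
}

deconv_bw <- function(dy, w, cache) {
  g <- cpp_deconv2_bw(as.double(cache$x), dim(cache$x), w, as.double(dy))
  list(dx = ftensor(g$dx, dim(cache$x)), dw = g$dw, db = g$db)
}

dwconv_fw <- function(x, w, k) {
  y <- cpp_depthwise_fw(as.double(x), dim(x), w, as.integer(k))
  list(y = ftensor(y, dim(x)), cache = list(x = x, k = as.integer(k)))
}

dwconv_bw <- function(dy, w, cache) {
  g <- cpp_depthwise_bw(as.double(cache$x), dim(cache$x), w, as.double(dy), cache$k)
  list(dx = ftensor(g$dx, dim(cache$x)), dw = g$dw)
}

# pointwise (1x1x1) convolution as a plain GEMM; w is (Cout x Cin)
pconv_fw <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  ym <- w %*% xm + b
  list(y = ftensor(ym, c(nrow(w), d[-1])), cache = list(xm = xm, d = d))
}

pconv_bw <- function(dy, w, cache) {
  dym <- matrix(dy, nrow = nrow(w))
  list(dx = ftensor(crossprod(w, dym), cache$d),
       dw = tcrossprod(dym, cache$xm),
       db = rowSums(dym))
}

# instance normalisation: per-channel over spatial locations, learnable
# scale gamma / shift beta, epsilon 1e-5
instnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[1]
  xm <- matrix(x, nrow = C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * gamma + beta
  list(y = ftensor(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

instnorm_bw <- function(dy, gamma, cache) {
  d <- cache$d
  C <- d[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dx = ftensor(dx, d), dgamma = dgamma, dbeta = dbeta)
}

gelu_fw <- function(x) {
  p <- pnorm(x)
  list(y = x * p, cache = list(x = x, p = p))
}

gelu_bw <- function(dy, cache) dy * (cache$p + cache$x * dnorm(cache$x))

lrelu_fw <- function(x, slope = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, cache = list(neg = neg, slope = slope))
}

lrelu_bw <- function(dy, cache) {
  dx <- dy
  dx[cache$neg] <- cache$slope * dy[cache$neg]
  dx
}

# parameter initialisation (He-style, ambient RNG)
init_conv_w <- function(cout, cin, k) {
  kv <- prod(k)
  matrix(rnorm(cout * cin * kv, sd = sqrt(2 / (cin * kv))), nrow = cout)
}
init_deconv_w <- function(cout, cin) {
  matrix(rnorm(cout * 8 * cin, sd = sqrt(2 / cin)), nrow = cout * 8)
}
init_dw_w <- function(c, k) {
  kv <- prod(k)
  matrix(rnorm(c * kv, sd = sqrt(2 / kv)), nrow = c)
}
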