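test_that("msca_params validates kernel extents", {
  expect_error(msca_params(4, dw_kernel = 4), "odd")
  expect_error(msca_params(4, branch_kernels = c(5, 7, 1)), "odd")
  expect_error(msca_params(0), ">= 1")
  p <- msca_params(8)
  expect_identical(p$branch_kernels, c(5L, 7L, 11L))
})

test_that("msca_init draws the full weight layout", {
  set.seed(1)
  w <- msca_init(msca_params(6))
  expect_identical(dim(w$dw), c(6L, 125L))
  expect_length(w$branches, 3)
  expect_identical(dim(w$branches[[2]]$wa), c(6L, 7L))
  expect_identical(dim(w$pw), c(6L, 6L))
  expect_length(w$pwb, 6)
})

test_that("msca_block preserves shape and is deterministic", {
  set.seed(2)
  w <- msca_init(msca_params(3))
  x <- mscaseg:::ftensor(rnorm(3 * 8 * 8 * 8), c(3, 8, 8, 8))
  y1 <- msca_block(x, w)
  y2 <- msca_block(x, w)
  expect_identical(dim(y1), dim(x))
  expect_identical(y1, y2)
  expect_error(msca_block(mscaseg:::ftensor(rnorm(2 * 8^3), c(2, 8, 8, 8)), w),
               "channels")
})

test_that("hand-constructed identity attention gives y = x * x", {
  # dw = centred delta, strips zero, pw = identity, pwb = 0:
  # attention equals the input, so the gated output is the square
  p <- msca_params(2)
  w <- msca_init(p)
  w$dw[] <- 0; w$dw[, (125 + 1) / 2] <- 1
  for (i in 1:3) for (nm in c("wa", "wb", "wc")) w$branches[[i]][[nm]][] <- 0
  w$pw <- diag(2)
  w$pwb <- c(0, 0)
  set.seed(3)
  x <- mscaseg:::ftensor(rnorm(2 * 6 * 6 * 6), c(2, 6, 6, 6))
  expect_equal(msca_block(x, w), x * x, tolerance = 1e-12)
})

test_that("strip branches factorise into per-axis extents", {
  # keeping one branch and an impulse attention path: the attention response
  # to a centred input impulse spans at most (dw + strip - 1) per axis
  p <- msca_params(1, dw_kernel = 3, branch_kernels = 5)
  set.seed(4)
  w <- msca_init(p)
  w$params <- p
  x <- array(0, c(1, 15, 15, 15))
  x[1, 8, 8, 8] <- 1
  x <- mscaseg:::ftensor(as.double(x), c(1L, 15L, 15L, 15L))
  # gate against an all-ones input so y equals the attention map itself
  ones <- mscaseg:::ftensor(rep(1, 15^3), c(1L, 15L, 15L, 15L))
  att_of <- function(inp) {
    f <- mscaseg:::msca_fw(inp, w)
    f$cache$atty
  }
  a <- att_of(x)
  # one strip per axis: per-axis reach is (3-1)/2 + (5-1)/2 = 3 voxels
  nz <- which(a != 0, arr.ind = TRUE)[, -1, drop = FALSE]
  expect_true(all(abs(nz - 8) <= 3))
  expect_gt(max(abs(nz - 8)), 1)  # strips reach beyond the dw kernel alone
  expect_identical(dim(att_of(ones)), dim(a))
})

test_that("msca_block is translation-equivariant in the interior", {
  set.seed(5)
  p <- msca_params(2, dw_kernel = 3, branch_kernels = c(3, 5))
  w <- msca_init(p)
  base <- array(rnorm(2 * 20 * 20 * 20), c(2, 20, 20, 20))
  shifted <- base
  shifted[, 3:20, , ] <- base[, 1:18, , ]
  y0 <- msca_block(mscaseg:::ftensor(base, dim(base)), w)
  y1 <- msca_block(mscaseg:::ftensor(shifted, dim(shifted)), w)
  # compare interiors away from both borders: attention reach is 3 voxels,
  # so v and v+2 both need their +/-3 neighbourhoods inside the volume and
  # inside the shifted copy's defined region
  m <- 6:15
  expect_equal(y1[, m + 2, m, m], y0[, m, m, m], tolerance = 1e-10)
})
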