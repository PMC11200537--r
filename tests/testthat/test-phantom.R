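test_that("phantom labels are nested shells with all four classes", {
  ph <- tiny_phantom()
  lab <- ph$labels$data
  expect_setequal(unique(as.vector(lab)), 0:3)
  d <- dim(lab)
  ctr <- (d + 1) %/% 2
  # centre voxel is WM, a corner is background
  expect_identical(lab[ctr[1], ctr[2], ctr[3]], 3L)
  expect_identical(lab[1, 1, 1], 0L)
  # nesting: every WM voxel lies within the middle shell radius of the centre
  r_wm <- max(sqrt(colSums((t(which(lab == 3L, arr.ind = TRUE)) - ctr)^2)))
  r_gm_min_shell <- 0.35 * d[1]
  expect_lt(r_wm, r_gm_min_shell + 2)
})

test_that("phantom intensities match per-class means", {
  ph <- tiny_phantom()
  img <- ph$volume$data
  lab <- ph$labels$data
  cfg <- phantom_config(shape = c(48, 48, 48))
  for (k in 1:3) {
    m <- mean(img[lab == k])
    expect_lt(abs(m - cfg$class_means[k]), 1)
  }
  expect_lt(abs(mean(img[lab == 0])), 1)
})

test_that("phantom generation is deterministic under seed", {
  cfg <- phantom_config(shape = c(24, 24, 24))
  a <- generate_phantom(cfg, seed = 5)
  b <- generate_phantom(cfg, seed = 5)
  c3 <- generate_phantom(cfg, seed = 6)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_false(identical(a$volume$data, c3$volume$data))
})

test_that("rician noise yields non-negative background mean shift", {
  cfg <- phantom_config(shape = c(24, 24, 24), noise_model = "rician")
  ph <- generate_phantom(cfg, seed = 2)
  # Rician |0 + complex noise| has positive mean in air
  expect_gt(mean(ph$volume$data[ph$labels$data == 0]), 1)
  expect_true(all(ph$volume$data >= 0))
})

test_that("bias field is multiplicative exp(poly) over [-1,1] coordinates", {
  v <- as_volume(array(1, c(9, 9, 9)))
  out <- apply_bias_field(v, c("1" = 0.5))
  expect_equal(out$data, array(exp(0.5), c(9, 9, 9)))
  outx <- apply_bias_field(v, c(x = 1))
  expect_equal(outx$data[1, 5, 5], exp(-1))
  expect_equal(outx$data[9, 5, 5], exp(1))
  expect_equal(outx$data[5, 5, 5], exp(0))
  # monotone along x for positive coefficient
  expect_true(all(diff(outx$data[, 5, 5]) > 0))
  expect_error(apply_bias_field(v, c(q = 1)), "not understood")
  expect_error(apply_bias_field(v, c(1)), "named")
})

test_that("phantom_config validates shell nesting", {
  expect_error(phantom_config(shell_radii = list(outer = c(0.3, 0.3, 0.3),
                                                 middle = c(0.35, 0.35, 0.35),
                                                 inner = c(0.2, 0.2, 0.2))),
               "nested")
  expect_error(phantom_config(noise_sd = -1), ">= 0")
})

test_that("corruption severity 0 is the identity for every mode", {
  ph <- tiny_phantom()
  for (m in c("erode", "dilate", "boundary_jitter", "class_swap")) {
    out <- corrupt_labels(ph$labels, corruption_spec(m, 0), seed = 1)
    expect_identical(out$data, ph$labels$data)
  }
})

test_that("erode shrinks and dilate grows the target class", {
  ph <- tiny_phantom()
  n_wm <- sum(ph$labels$data == 3L)
  er <- corrupt_labels(ph$labels, corruption_spec("erode", 2, target_class = 3))
  di <- corrupt_labels(ph$labels, corruption_spec("dilate", 2, target_class = 3))
  expect_lt(sum(er$data == 3L), n_wm)
  expect_gt(sum(di$data == 3L), n_wm)
  # erosion sends removed voxels to background, leaves other classes alone
  expect_identical(sum(er$data == 2L), sum(ph$labels$data == 2L))
  expect_gt(sum(er$data == 0L), sum(ph$labels$data == 0L))
  # dilation only converts voxels adjacent to the original mask
  changed <- which(di$data != ph$labels$data)
  expect_true(all(di$data[changed] == 3L))
})

test_that("boundary jitter only relabels boundary voxels, deterministically", {
  ph <- tiny_phantom()
  spec <- corruption_spec("boundary_jitter", 2)
  a <- corrupt_labels(ph$labels, spec, seed = 4)
  b <- corrupt_labels(ph$labels, spec, seed = 4)
  expect_identical(a$data, b$data)
  changed <- a$data != ph$labels$data
  expect_gt(sum(changed), 0)
  # changed voxels must have had a differently-labelled 6-neighbour
  bnd <- mscaseg:::.boundary_mask(ph$labels$data)
  expect_true(all(bnd[changed]))
})

test_that("class swap relabels within foreground at the expected rate", {
  ph <- tiny_phantom()
  out <- corrupt_labels(ph$labels, corruption_spec("class_swap", 2), seed = 9)
  changed <- out$data != ph$labels$data
  # swaps only happen on foreground, never create background
  expect_true(all(ph$labels$data[changed] != 0L))
  expect_true(all(out$data[changed] %in% 1:3))
  rate <- sum(changed) / sum(ph$labels$data != 0L)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
})
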