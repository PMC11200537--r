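test_that("as_volume and as_labelmap validate their inputs", {
  expect_error(as_volume(matrix(0, 2, 2)), "3 spatial axes")
  expect_error(as_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(as_labelmap(array(5L, c(2, 2, 2))), "label values")
  v <- as_volume(array(1.5, c(2, 3, 4)), spacing = c(1, 2, 3))
  expect_s3_class(v, "msca_volume")
  expect_identical(dim(v$data), c(2L, 3L, 4L))
  expect_equal(diag(v$affine), c(1, 2, 3, 1))
})

test_that("NIfTI round trip preserves data, spacing and labels", {
  tmp <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(tmp))
  set.seed(1)
  v <- as_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(1, 1.5, 2))
  write_volume(v, tmp)
  v2 <- read_volume(tmp)
  expect_equal(v2$data, v$data, tolerance = 0)
  expect_equal(v2$spacing, v$spacing)

  lab <- as_labelmap(array(sample(0:3, 60, TRUE), c(5, 4, 3)))
  write_volume(lab, tmp)
  l2 <- read_volume(tmp, labels = TRUE)
  expect_s3_class(l2, "msca_labels")
  expect_identical(l2$data, lab$data)
})

test_that("read_volume rejects non-3D images and missing files", {
  expect_error(read_volume(tempfile()), "not found")
  tmp <- tempfile(fileext = ".nii")
  on.exit(unlink(tmp))
  img <- RNifti::asNifti(array(0, c(3, 3, 3, 2)))
  RNifti::writeNifti(img, tmp)
  expect_error(read_volume(tmp), "3-dimensional")
})

test_that("one_hot_encode produces exact indicator channels", {
  lab <- array(c(0L, 1L, 2L, 3L, 3L, 0L, 1L, 2L), c(2, 2, 2))
  oh <- one_hot_encode(lab)
  expect_identical(dim(oh), c(4L, 2L, 2L, 2L))
  # channel sums are 1 at every voxel
  expect_true(all(apply(oh, 2:4, sum) == 1))
  for (k in 0:3)
    expect_equal(oh[k + 1, , , ], array(as.numeric(lab == k), dim(lab)))
  expect_error(one_hot_encode(array(4L, c(1, 1, 1))), ">= K")
})

test_that("sample_patch is deterministic, aligned, and respects bounds", {
  ph <- tiny_phantom()
  p1 <- sample_patch(ph$volume, ph$labels, 16, seed = 3)
  p2 <- sample_patch(ph$volume, ph$labels, 16, seed = 3)
  expect_identical(p1, p2)
  expect_identical(dim(p1$image), c(16L, 16L, 16L))
  expect_identical(dim(p1$labels), c(16L, 16L, 16L))
  o <- p1$origin
  expect_true(all(o >= 0) && all(o + 16 <= dim(ph$volume$data)))
  # alignment: patch content equals the subarray at origin
  ix <- lapply(1:3, function(a) (o[a] + 1):(o[a] + 16))
  expect_equal(p1$image, ph$volume$data[ix[[1]], ix[[2]], ix[[3]]])
  expect_identical(p1$labels, ph$labels$data[ix[[1]], ix[[2]], ix[[3]]])
})

test_that("foreground-biased patches contain foreground", {
  ph <- tiny_phantom()
  for (s in 1:10) {
    p <- sample_patch(ph$volume, ph$labels, 16, seed = s, fg_bias = 1)
    expect_gt(sum(p$labels != 0), 0)
  }
  expect_error(sample_patch(ph$volume, ph$labels, 64, seed = 1), "exceeds")
  expect_error(sample_patch(ph$volume, ph$labels, 16, seed = 1, fg_bias = 2),
               "fg_bias")
})
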