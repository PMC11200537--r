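test_that("poly_lr matches the closed form exactly", {
  cfg <- train_config(max_epoch = 500L)
  expect_equal(poly_lr(0, cfg), 0.01)
  expect_equal(poly_lr(500, cfg), 0)
  expect_equal(poly_lr(123, cfg), 0.01 * (1 - 123 / 500)^0.9)
  expect_error(poly_lr(-1, cfg), "out of range")
  expect_error(poly_lr(501, cfg), "out of range")
})

test_that("kfold_split partitions the cases", {
  folds <- kfold_split(10, 5, seed = 3)
  expect_length(folds, 5)
  all_val <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(all_val, 0:9)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$val)), 0:9)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(f$val, 2)
  }
  # uneven split sizes differ by at most one
  sizes <- vapply(kfold_split(11, 4, seed = 1), function(f) length(f$val),
                  integer(1))
  expect_lte(diff(range(sizes)), 1)
  expect_error(kfold_split(3, 5), "exceed")
})

test_that("augment_patch transforms image and labels identically", {
  ph <- tiny_phantom()
  pair <- sample_patch(ph$volume, ph$labels, 16, seed = 1, fg_bias = 1)
  for (s in 1:8) {
    out <- augment_patch(pair, seed = s)
    expect_identical(dim(out$image), dim(pair$image))
    # the multiset of (intensity, label) voxel pairs is invariant under
    # any rigid axis permutation/flip
    expect_equal(sort(out$image), sort(pair$image))
    expect_identical(sort(as.vector(out$labels)), sort(as.vector(pair$labels)))
    # pairing preserved: per-class intensity means unchanged
    for (k in sort(unique(as.vector(pair$labels))))
      expect_equal(mean(out$image[out$labels == k]),
                   mean(pair$image[pair$labels == k]))
  }
  expect_identical(augment_patch(pair, seed = 4), augment_patch(pair, seed = 4))
  expect_identical(augment_patch(pair, seed = 4, flags = character(0)), pair)
  expect_error(augment_patch(pair, seed = 1, flags = "zoom"), "unknown")
})

test_that("train_model logs schedule-exact learning rates and loss parts", {
  ph <- tiny_phantom()
  cfg <- train_config(max_epoch = 2L, iters_per_epoch = 2L, patch_size = 32L,
                      batch_size = 1L, seed = 5L)
  arch <- arch_config(stage_channels = c(2, 3, 4, 5, 5))
  fit <- train_model(list(ph), cfg, arch)
  log <- fit$log
  expect_identical(nrow(log), 4L)
  expect_equal(log$lr, poly_lr(log$epoch - 1L, cfg))
  expect_equal(log$l_total, log$l_seg + cfg$lambda_ * log$l_data)
  expect_true(all(log$w_data_mean >= 0 & log$w_data_mean <= 1))
  expect_s3_class(fit$net, "msca_network")
})

test_that("lambda = 0 training logs an identically zero data loss", {
  ph <- tiny_phantom()
  cfg <- train_config(max_epoch = 1L, iters_per_epoch = 3L, patch_size = 32L,
                      batch_size = 1L, lambda_ = 0, seed = 6L)
  arch <- arch_config(stage_channels = c(2, 3, 4, 5, 5))
  fit <- train_model(list(ph), cfg, arch)
  expect_true(all(fit$log$l_data == 0))
  expect_true(all(fit$log$l_seg > 0))
})

test_that("training is deterministic under the seed", {
  ph <- tiny_phantom()
  cfg <- train_config(max_epoch = 1L, iters_per_epoch = 2L, patch_size = 32L,
                      batch_size = 1L, seed = 9L)
  arch <- arch_config(stage_channels = c(2, 3, 4, 5, 5))
  a <- train_model(list(ph), cfg, arch)
  b <- train_model(list(ph), cfg, arch)
  expect_equal(a$log$l_total, b$log$l_total, tolerance = 1e-6)
  expect_identical(a$net$params, b$net$params)
})

test_that("predict_volume returns a label map of the input shape", {
  ph <- tiny_phantom()
  net <- build_network(arch_config(stage_channels = c(2, 3, 4, 5, 5)), seed = 1)
  cfg <- train_config(patch_size = 32L)
  pred <- predict_volume(net, ph$volume, cfg)
  expect_s3_class(pred, "msca_labels")
  expect_identical(dim(pred$data), dim(ph$volume$data))
  expect_true(all(pred$data %in% 0:3))
})

test_that("train_config validates arguments", {
  expect_error(train_config(initial_lr = 0), "> 0")
  expect_error(train_config(momentum = 1), "momentum")
  expect_error(train_config(patch_size = 30), "divisible by 32")
  expect_error(train_config(augment = "elastic"), "unknown")
})

test_that("checkpoint round trip preserves the network", {
  net <- build_network(arch_config(stage_channels = c(2, 3, 4, 5, 5)), seed = 3)
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  save_checkpoint(net, tmp)
  net2 <- load_checkpoint(tmp)
  expect_identical(net2$params, net$params)
  saveRDS(1:3, tmp)
  expect_error(load_checkpoint(tmp), "not a network")
})

test_that("read_config fills defaults and honours overrides", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(c("train:", "  initial_lr: 0.02", "  max_epoch: 7",
               "canny:", "  sigma: 2.0"), tmp)
  cfg <- read_config(tmp)
  expect_equal(cfg$train$initial_lr, 0.02)
  expect_identical(cfg$train$max_epoch, 7L)
  expect_equal(cfg$canny$sigma, 2)
  expect_equal(cfg$train$canny$sigma, 2)
  expect_identical(cfg$arch$stage_channels, c(32L, 64L, 128L, 256L, 320L))
  expect_equal(cfg$loss$lambda_, 1)
})
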