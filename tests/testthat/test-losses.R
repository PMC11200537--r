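test_that("dice_loss is 0 for perfect one-hot and rises with disagreement", {
  lab <- array(c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L), c(2, 2, 2))
  G <- one_hot_encode(lab)
  expect_lt(dice_loss(G, G), 1e-4)
  # uniform prediction over a toy: hand-computed value
  P <- array(0.25, dim(G))
  # per class k: 2*0.25*n_k / (8*0.0625 + n_k + eps)
  nk <- c(sum(lab == 1), sum(lab == 2), sum(lab == 3))
  expected <- 1 - mean(2 * 0.25 * nk / (8 * 0.0625 + nk + 1e-5))
  expect_equal(dice_loss(P, G), expected, tolerance = 1e-12)
  expect_error(dice_loss(P, G[, , , 1, drop = FALSE]), "identical shapes")
})

test_that("cross_entropy_loss matches hand computation over all voxels", {
  lab <- array(c(0L, 1L, 2L, 3L), c(4, 1, 1))
  P <- ftensor(rep(c(0.7, 0.1, 0.1, 0.1), 4), c(4, 4, 1, 1))
  P[, 2, 1, 1] <- c(0.1, 0.6, 0.2, 0.1)
  P[, 3, 1, 1] <- c(0.1, 0.2, 0.5, 0.2)
  P[, 4, 1, 1] <- c(0.25, 0.25, 0.25, 0.25)
  cfg <- loss_config()
  # all voxels, background included: its probability is a supervised target
  expect_equal(cross_entropy_loss(P, lab, cfg),
               mean(-log(c(0.7, 0.6, 0.5, 0.25))), tolerance = 1e-12)
  # uniform prediction over K = 4 gives exactly ln 4
  U <- ftensor(rep(0.25, 16), c(4, 4, 1, 1))
  expect_equal(cross_entropy_loss(U, lab, cfg), log(4), tolerance = 1e-12)
  # epsilon clamp bounds the loss on a confident wrong prediction
  W <- ftensor(rep(c(1, 0, 0, 0), 4), c(4, 4, 1, 1))
  expect_equal(cross_entropy_loss(W, lab, cfg),
               mean(-log(pmax(c(1, 0, 0, 0), cfg$epsilon))), tolerance = 1e-12)
})

test_that("segmentation_loss combines stages with the deep-supervision weights", {
  set.seed(4)
  lab <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  p_full <- channel_softmax(ftensor(rnorm(4 * 64), c(4, 4, 4, 4)))
  p_half <- channel_softmax(ftensor(rnorm(4 * 8), c(4, 2, 2, 2)))
  cfg <- loss_config(ds_weights = c(0.25, 0.5))
  G <- one_hot_encode(lab)
  # manual: final stage at native resolution needs no renormalisation
  l_full <- dice_loss(p_full, G) + cross_entropy_loss(p_full, lab, cfg)
  l_total <- segmentation_loss(list(p_half, p_full), lab, cfg)
  # subtracting the full-res term leaves 0.25 * (upsampled half-res term)
  rest <- l_total - 0.5 * l_full
  expect_gt(rest, 0)
  expect_lt(rest, 0.25 * 10)
  expect_error(segmentation_loss(list(p_full), lab, cfg), "ds_weights")
})

test_that("data_quality_loss scales cross-entropy by w_data", {
  set.seed(5)
  lab <- array(sample(0:3, 27, TRUE), c(3, 3, 3))
  P <- channel_softmax(ftensor(rnorm(4 * 27), c(4, 3, 3, 3)))
  cfg <- loss_config()
  ce <- cross_entropy_loss(P, lab, cfg)
  expect_equal(data_quality_loss(P, lab, 0.4, cfg), 0.4 * ce)
  expect_equal(data_quality_loss(P, lab, 0, cfg), 0)
  expect_error(data_quality_loss(P, lab, 1.2, cfg), "\\[0, 1\\]")
})

test_that("total_loss = l_seg + lambda * l_data and lambda = 0 kills l_data", {
  set.seed(6)
  lab <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  stages <- list(channel_softmax(ftensor(rnorm(4 * 8), c(4, 2, 2, 2))),
                 channel_softmax(ftensor(rnorm(4 * 64), c(4, 4, 4, 4))))
  cfg <- loss_config(ds_weights = c(0.25, 0.5), lambda_ = 1)
  tl <- total_loss(stages, lab, 0.8, cfg)
  expect_equal(tl$total, tl$l_seg + tl$l_data)
  expect_equal(tl$l_seg, segmentation_loss(stages, lab, cfg))

  cfg0 <- loss_config(ds_weights = c(0.25, 0.5), lambda_ = 0)
  tl0 <- total_loss(stages, lab, 0.8, cfg0)
  expect_equal(tl0$total, tl0$l_seg)
  lg0 <- total_loss_grad(lapply(stages, log), lab, 0.8, cfg0)
  expect_equal(lg0$loss$l_data, 0)
})

test_that("total_loss_grad matches finite differences", {
  set.seed(7)
  lab <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  logits <- list(ftensor(rnorm(4 * 8), c(4, 2, 2, 2)),
                 ftensor(rnorm(4 * 64), c(4, 4, 4, 4)))
  cfg <- loss_config(ds_weights = c(0.25, 0.5))
  lg <- total_loss_grad(logits, lab, 0.7, cfg)
  h <- 1e-6
  for (s in 1:2) {
    idx <- sample(length(logits[[s]]), 6)
    for (i in idx) {
      lp <- logits; lp[[s]][i] <- lp[[s]][i] + h
      lm <- logits; lm[[s]][i] <- lm[[s]][i] - h
      fd <- (total_loss_grad(lp, lab, 0.7, cfg)$loss$total -
             total_loss_grad(lm, lab, 0.7, cfg)$loss$total) / (2 * h)
      expect_equal(lg$dlogits[[s]][i], fd, tolerance = 1e-4)
    }
  }
  # loss value consistent with the softmaxed total_loss
  probs <- lapply(logits, channel_softmax)
  tl <- total_loss(probs, lab, 0.7, cfg)
  expect_equal(lg$loss$total, tl$total, tolerance = 1e-10)
})

test_that("loss_config validates its arguments", {
  expect_error(loss_config(ds_weights = c(0.5, 0)), "> 0")
  expect_error(loss_config(lambda_ = -1), ">= 0")
  expect_error(loss_config(epsilon = 0), "> 0")
})
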