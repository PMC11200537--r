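test_that("arch_config encodes the five-stage layout", {
  cfg <- arch_config()
  expect_identical(cfg$n_stages, 5L)
  expect_identical(cfg$stage_block_type, c("conv", "conv", "msca", "msca", "msca"))
  expect_identical(cfg$dec_block_type, c("msca", "msca", "conv", "conv", "conv"))
  abl <- arch_config(use_msca = FALSE)
  expect_true(all(abl$stage_block_type == "conv"))
  expect_error(arch_config(stage_channels = c(8, 16)), "length 5")
  tiny <- arch_config_tiny()
  expect_identical(tiny$stage_channels, c(8L, 16L, 32L, 64L, 64L))
})

test_that("build_network is deterministic under seed", {
  cfg <- arch_config(stage_channels = c(2, 3, 4, 5, 5))
  a <- build_network(cfg, seed = 11)
  b <- build_network(cfg, seed = 11)
  c3 <- build_network(cfg, seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c3$params))
  expect_gt(n_parameters(a), 0)
})

test_that("describe_network tabulates stages and counts all parameters", {
  net <- build_network(arch_config(stage_channels = c(2, 3, 4, 5, 5)), seed = 1)
  df <- describe_network(net)
  expect_identical(nrow(df), 10L)
  expect_equal(df$factor[df$part == "encoder"], 2^(1:5))
  expect_equal(df$factor[df$part == "decoder"], 2^(4:0))
  expect_equal(sum(df$n_params), n_parameters(net))
})

test_that("forward_pass emits five probability maps at ascending resolution", {
  net <- build_network(arch_config(stage_channels = c(2, 3, 4, 5, 5)), seed = 2)
  patch <- array(rnorm(32^3), c(32, 32, 32))
  fp <- forward_pass(net, patch)
  expect_identical(fp$scale_factors, c(16L, 8L, 4L, 2L, 1L))
  dims <- c(2, 4, 8, 16, 32)
  for (s in 1:5) {
    o <- fp$outputs[[s]]
    expect_identical(dim(o), c(4L, rep(as.integer(dims[s]), 3)))
    expect_true(all(o >= 0))
    sums <- apply(o, 2:4, sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  }
  expect_error(forward_pass(net, array(0, c(30, 32, 32))), "divisible by 32")
})

test_that("analytic network gradients match finite differences", {
  net <- build_network(arch_config(stage_channels = c(2, 3, 4, 5, 5)), seed = 7)
  set.seed(8)
  patch <- array(rnorm(32^3), c(32, 32, 32))
  lab <- array(sample(0:3, 32^3, TRUE), c(32, 32, 32))
  cfg <- loss_config()
  x <- mscaseg:::ftensor(as.double(patch), c(1L, 32L, 32L, 32L))
  fw <- mscaseg:::net_forward(net, x, keep_cache = TRUE)
  lg <- total_loss_grad(fw$logits, lab, 0.5, cfg)
  gn <- mscaseg:::net_backward(net, fw$caches, lg$dlogits)
  h <- 1e-5
  check <- function(get, set, ganal, n = 2) {
    pv <- get(net$params)
    idx <- sample(length(pv), n)
    for (i in idx) {
      fd <- 0
      for (sgn in c(1, -1)) {
        p2 <- pv; p2[i] <- p2[i] + sgn * h
        nl <- net; nl$params <- set(nl$params, p2)
        f2 <- mscaseg:::net_forward(nl, x, keep_cache = FALSE)
        fd <- fd + sgn * total_loss_grad(f2$logits, lab, 0.5, cfg)$loss$total / (2 * h)
      }
      expect_equal(ganal[i], fd, tolerance = 5e-2)
    }
  }
  check(function(p) p$dec[[5]]$head$w,
        function(p, v) { p$dec[[5]]$head$w <- matrix(v, 4); p },
        gn$dec[[5]]$head$w)
  check(function(p) p$enc[[4]]$block$msca$pw,
        function(p, v) { p$enc[[4]]$block$msca$pw <- matrix(v, 5); p },
        gn$enc[[4]]$block$msca$pw)
})
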