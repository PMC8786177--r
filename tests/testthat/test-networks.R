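ns <- asNamespace("dbtdeblur")

test_that("Phase-1 network preserves shape, seeds deterministically, zeroes out", {
  sp <- phase1_spec(n_blocks = 2L, n_filters = 6L, seed = 9)
  net <- build_phase1(sp)
  net2 <- build_phase1(sp)
  expect_identical(net$par, net2$par)

  dims <- c(12L, 12L, 12L)
  x <- matrix(rnorm(prod(dims)), 1)
  y <- ns$phase1_forward(net, x, dims)$y
  expect_identical(dim(y), as.integer(c(1, prod(dims))))

  # all-zero convolution weights and biases give identically zero output
  z <- net; z$par <- lapply(z$par, function(p) p * 0)
  expect_equal(max(abs(ns$phase1_forward(z, x, dims)$y)), 0)

  expect_error(ns$phase1_forward(net, matrix(0, 1, 4), c(2L, 2L, 1L)), "kernel")
  expect_error(phase1_spec(n_blocks = 0), "n_blocks")
})

test_that("analytic receptive fields match the layer-recursion oracles", {
  # independent recursion oracle: r <- r + (k - 1) * jump per layer
  rf_seq <- function(layers) {
    r <- 1; j <- 1
    for (l in layers) {
      r <- r + (l[["k"]] - 1) * j
      j <- j * l[["s"]]
    }
    r
  }
  # Phase 1: in-conv + 2 convs per block + out-conv, all 3^3 stride 1
  p1_layers <- rep(list(c(k = 3, s = 1)), 2 * 10 + 2)
  expect_equal(receptive_field_phase1(phase1_spec(10L, 40L)), rf_seq(p1_layers))
  expect_equal(receptive_field_phase1(phase1_spec(10L, 40L)), 45L)

  # Phase 2 encoder bottleneck: (conv conv pool) x 4 + conv conv
  p2_layers <- c(rep(list(c(k = 3, s = 1), c(k = 3, s = 1), c(k = 2, s = 2)), 4),
                 list(c(k = 3, s = 1), c(k = 3, s = 1)))
  expect_equal(receptive_field_phase2(phase2_spec()), rf_seq(p2_layers))
  tr <- receptive_field_phase2(phase2_spec(), trace = TRUE)
  expect_true(all(c(5, 6, 14, 16, 32, 36, 68, 76, 140) %in% tr))

  # critic stack lands near the 144 x 144 patch size
  expect_equal(receptive_field_critic(discriminator_spec()), 142L)
  expect_lt(abs(receptive_field_critic(discriminator_spec()) - 144) / 144, 0.05)
})

test_that("U-Net doubles filters per level and preserves full-size slices", {
  sp <- phase2_spec()  # 32 base filters, 4 levels
  net <- build_phase2(sp)
  widths <- vapply(1:4, function(l) dim(net$par[[sprintf("enc%d.w1", l)]])[1], 0L)
  expect_identical(widths, c(32L, 64L, 128L, 256L))
  expect_identical(dim(net$par$bot.w1)[1], 512L)

  # full-scale coronal slice passes through unchanged in shape
  dims <- c(288L, 144L)
  y <- ns$phase2_forward(net, matrix(rnorm(prod(dims)), 1), dims)$y
  expect_identical(dim(y), as.integer(c(1, prod(dims))))

  sp_small <- phase2_spec(base_filters = 4L, pooling_levels = 2L, seed = 2)
  nsm <- build_phase2(sp_small)
  expect_error(ns$phase2_forward(nsm, matrix(0, 1, 18 * 12), c(18L, 12L)),
               "divisible")
})

test_that("backpropagated gradients match finite differences in every network", {
  fd <- function(loss_fn, par, nm, i, eps = 1e-6) {
    p <- par; p[[nm]][i] <- p[[nm]][i] + eps; up <- loss_fn(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps; dn <- loss_fn(p)
    (up - dn) / (2 * eps)
  }
  set.seed(31)

  net <- build_phase1(phase1_spec(2L, 4L, seed = 3))
  dims <- c(6L, 6L, 6L)
  x <- matrix(rnorm(216), 1); tgt <- matrix(rnorm(216), 1)
  lf <- function(par) { n <- net; n$par <- par
    sum((ns$phase1_forward(n, x, dims)$y - tgt)^2) }
  fw <- ns$phase1_forward(net, x, dims, keep = TRUE)
  bw <- ns$phase1_backward(net, fw$cache, 2 * (fw$y - tgt), dims)
  for (nm in c("in.w", "blk1.w1", "blk2.w2", "out.w", "blk1.b1")) {
    i <- sample(length(net$par[[nm]]), 1)
    expect_equal(bw$grads[[nm]][i], fd(lf, net$par, nm, i), tolerance = 1e-5)
  }

  net2 <- build_phase2(phase2_spec(base_filters = 3L, pooling_levels = 2L, seed = 5))
  dims2 <- c(8L, 8L)
  x2 <- matrix(rnorm(64), 1); t2 <- matrix(rnorm(64), 1)
  lf2 <- function(par) { n <- net2; n$par <- par
    sum((ns$phase2_forward(n, x2, dims2)$y - t2)^2) }
  fw2 <- ns$phase2_forward(net2, x2, dims2, keep = TRUE)
  bw2 <- ns$phase2_backward(net2, fw2$cache, 2 * (fw2$y - t2), dims2)
  for (nm in c("enc1.w1", "enc2.w2", "bot.w1", "dec2.wu", "dec1.w1", "out.w")) {
    i <- sample(length(net2$par[[nm]]), 1)
    expect_equal(bw2$grads[[nm]][i], fd(lf2, net2$par, nm, i), tolerance = 1e-5)
  }

  cr <- build_discriminator(discriminator_spec(base_filters = 4L, seed = 6))
  dimsc <- c(16L, 16L)
  xc <- matrix(rnorm(256), 1)
  lfc <- function(par) { n <- cr; n$par <- par; ns$critic_forward(n, xc, dimsc)$value }
  fwc <- ns$critic_forward(cr, xc, dimsc, keep = TRUE)
  bwc <- ns$critic_backward(cr, fwc$cache)
  for (nm in c("c1.w", "c3.w", "c5.w", "out.w", "c2.b")) {
    i <- sample(length(cr$par[[nm]]), 1)
    expect_equal(bwc$grads[[nm]][i], fd(lfc, cr$par, nm, i), tolerance = 1e-5)
  }
  # critic gradient w.r.t. its input (the WGAN-GP penalty ingredient)
  i <- 100L
  xp <- xc; xp[1, i] <- xp[1, i] + 1e-6
  xm <- xc; xm[1, i] <- xm[1, i] - 1e-6
  num <- (ns$critic_forward(cr, xp, dimsc)$value -
            ns$critic_forward(cr, xm, dimsc)$value) / 2e-6
  expect_equal(bwc$dx[1, i], num, tolerance = 1e-5)
})

test_that("checkpoints reload to a bit-identical forward pass", {
  net <- build_phase1(phase1_spec(2L, 4L, seed = 12))
  model <- ns$new_trained_model(net, 1L, list(train = 0.1), train_config(),
                                patch_side = 8L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  x <- matrix(rnorm(512), 1)
  expect_identical(ns$phase1_forward(back$net, x, c(8L, 8L, 8L))$y,
                   ns$phase1_forward(net, x, c(8L, 8L, 8L))$y)
})
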