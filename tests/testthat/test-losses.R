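ns <- asNamespace("dbtdeblur")

test_that("MAE matches hand computations and the median-minimizer property", {
  expect_equal(loss_mae(matrix(1:4, 2), matrix(1:4, 2)), 0)
  pred <- matrix(c(0, 2, 1, 3), 2)   # [[0,1],[2,3]] row-wise
  tgt <- matrix(1, 2, 2)
  expect_equal(loss_mae(pred, tgt), 1.0)
  expect_error(loss_mae(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")

  # minimizing MAE over constants lands on the median (1D brute force)
  set.seed(8)
  v <- rnorm(31)
  cs <- seq(-3, 3, by = 0.001)
  obj <- vapply(cs, function(cc) mean(abs(cc - v)), 0)
  expect_equal(cs[which.min(obj)], median(v), tolerance = 2e-3)
})

test_that("adversarial loss reduces to the penalty for a constant critic", {
  sp <- discriminator_spec(base_filters = 4L, seed = 2)
  d <- build_discriminator(sp)
  d$par <- lapply(d$par, function(p) p * 0)   # D == 0 everywhere, zero gradient
  dims <- c(16L, 16L)
  fake <- matrix(runif(256), 1); real <- matrix(runif(256), 1)
  l <- loss_adversarial(d, fake, real, dims, eta = 0.1, seed = 1)
  expect_equal(as.numeric(l), 0.1)   # eta * (0 - 1)^2

  # random critic: the value decomposes exactly into its Eq parts, and the
  # reported gradient norm matches a directional finite difference
  d2 <- build_discriminator(sp)
  l2 <- loss_adversarial(d2, fake, real, dims, eta = 0.1, seed = 5)
  parts <- attr(l2, "parts")
  expect_equal(as.numeric(l2),
               parts["d_fake"] - parts["d_real"] +
                 0.1 * (parts["grad_norm"] - 1)^2,
               ignore_attr = TRUE)
  set.seed(5)
  epsu <- runif(1)
  xhat <- epsu * real + (1 - epsu) * fake
  fh <- ns$critic_forward(d2, xhat, dims, keep = TRUE)
  gx <- ns$critic_backward(d2, fh$cache)$dx
  u <- gx / sqrt(sum(gx^2))
  fdd <- (ns$critic_forward(d2, xhat + 1e-6 * u, dims)$value -
            ns$critic_forward(d2, xhat - 1e-6 * u, dims)$value) / 2e-6
  expect_equal(fdd, sqrt(sum(gx^2)), tolerance = 1e-5)
})

test_that("perceptual loss equals an independent plain-R reimplementation", {
  fx <- build_feature_extractor(base_filters = 2L, seed = 7)
  dims <- c(16L, 16L)
  pred <- matrix(rnorm(256), 1)
  tgt <- matrix(rnorm(256), 1)
  expect_equal(loss_perceptual(fx, pred, pred, dims), 0)
  expect_error(loss_perceptual(NULL, pred, tgt, dims), "extractor")

  # brute-force oracle: direct loops over channels/offsets, no shared code
  conv_ref <- function(x, w, b, nx, ny) {
    cin <- dim(w)[2]; cout <- dim(w)[1]
    off <- as.matrix(expand.grid(-1:1, -1:1))
    y <- matrix(0, cout, nx * ny)
    for (jy in seq_len(ny)) for (jx in seq_len(nx)) {
      acc <- rep(0, cout)
      for (k in seq_len(9)) {
        sx <- jx + off[k, 1]; sy <- jy + off[k, 2]
        if (sx >= 1 && sx <= nx && sy >= 1 && sy <= ny)
          acc <- acc + w[, , k, drop = FALSE][, , 1] %*%
            x[, sx + nx * (sy - 1)]
      }
      y[, jx + nx * (jy - 1)] <- acc + b
    }
    y
  }
  pool_ref <- function(x, nx, ny) {
    y <- matrix(0, nrow(x), (nx / 2) * (ny / 2))
    for (jy in seq_len(ny / 2)) for (jx in seq_len(nx / 2)) {
      cols <- c((2 * jx - 1) + nx * (2 * jy - 2), (2 * jx) + nx * (2 * jy - 2),
                (2 * jx - 1) + nx * (2 * jy - 1), (2 * jx) + nx * (2 * jy - 1))
      y[, jx + (nx / 2) * (jy - 1)] <- apply(x[, cols, drop = FALSE], 1, max)
    }
    y
  }
  fwd_ref <- function(img) {
    h <- rbind(img, img, img)
    h <- (h - 0.449) / 0.226
    nx <- dims[1]; ny <- dims[2]
    for (i in seq_along(fx$widths)) {
      h <- conv_ref(h, fx$par[[sprintf("c%d.w", i)]], fx$par[[sprintf("c%d.b", i)]],
                    nx, ny)
      h <- pmax(h, 0)
      if (i %in% fx$pool_after) {
        h <- pool_ref(h, nx, ny); nx <- nx / 2; ny <- ny / 2
      }
    }
    h
  }
  fa <- fwd_ref(pred); fb <- fwd_ref(tgt)
  want <- sum((fa - fb)^2) / length(fa)
  expect_equal(loss_perceptual(fx, pred, tgt, dims), want, tolerance = 1e-6)
})

test_that("combined objectives weight their components as configured", {
  cfg <- loss_config()
  expect_equal(cfg$lambda1, 0.001)
  expect_equal(cfg$lambda2, 0.05)
  expect_equal(cfg$eta, 0.1)
  expect_equal(loss_combined("pl-mae", mae = 0.2, pl = 1.0, config = cfg), 0.25)
  expect_equal(loss_combined("al-mae", mae = 0.2, al = 3,
                             config = loss_config(lambda1 = 0)), 0.2)
  expect_equal(loss_combined("mae", mae = 0.7), 0.7)
  expect_error(loss_combined("al-mae", mae = 0.1), "adversarial")
  expect_error(loss_combined("pl-mae", mae = 0.1), "perceptual")
  expect_error(loss_combined("huber", mae = 0.1))
  expect_error(loss_config(lambda1 = -1))
})
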