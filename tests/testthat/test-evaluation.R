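ns <- asNamespace("dbtdeblur")

make_vol <- function(arr, voxel = 1) attenuation_volume(arr, voxel)

test_that("mean MSE matches hand examples and is symmetric", {
  z <- make_vol(array(0, c(2, 2, 1)))
  o <- make_vol(array(1, c(2, 2, 1)))
  expect_equal(mse_mean(list(z), list(o))$mean, 1.0)
  expect_equal(mse_mean(list(o), list(o))$mean, 0)
  set.seed(1)
  a <- make_vol(array(rnorm(64), c(4, 4, 4)))
  b <- make_vol(array(rnorm(64), c(4, 4, 4)))
  expect_equal(mse_mean(list(a), list(b), "coronal")$mean,
               mse_mean(list(b), list(a), "coronal")$mean)
  expect_error(mse_mean(list(a), list(make_vol(array(0, c(2, 2, 2))))), "shape")
})

test_that("GRMSE vanishes for identical and for constant images", {
  cst1 <- make_vol(array(3, c(4, 4, 4)))
  cst2 <- make_vol(array(-1, c(4, 4, 4)))
  expect_equal(grmse_mean(list(cst1), list(cst2))$mean, 0)
  set.seed(2)
  a <- make_vol(array(rnorm(64), c(4, 4, 4)))
  expect_equal(grmse_mean(list(a), list(a))$mean, 0)
})

test_that("metrics match independent brute-force evaluation on 8x8 fixtures", {
  set.seed(7)
  m <- 3
  ref <- lapply(1:m, function(i) make_vol(array(rnorm(8 * 8 * 8), c(8, 8, 8))))
  tst <- lapply(1:m, function(i) make_vol(array(rnorm(8 * 8 * 8), c(8, 8, 8))))
  ctr <- 8 %/% 2 + 1

  # Eq-7 oracle: explicit double sum over volumes and pixels
  acc <- 0
  for (i in 1:m) {
    y <- unclass(ref[[i]])[, , ctr]; yt <- unclass(tst[[i]])[, , ctr]
    s <- 0
    for (r in 1:8) for (cc in 1:8) s <- s + (y[r, cc] - yt[r, cc])^2
    acc <- acc + s / 64
  }
  expect_equal(mse_mean(ref, tst)$mean, acc / m, tolerance = 1e-12)

  # Eq-8 oracle: gradient magnitude by explicit loops (replicated edges),
  # per-image root before averaging
  gmag <- function(img) {
    out <- img * 0
    for (r in 1:8) for (cc in 1:8) {
      rp <- min(r + 1, 8); rm <- max(r - 1, 1)
      cp <- min(cc + 1, 8); cm <- max(cc - 1, 1)
      gx <- (img[rp, cc] - img[rm, cc]) / 2
      gy <- (img[r, cp] - img[r, cm]) / 2
      out[r, cc] <- sqrt(gx^2 + gy^2)
    }
    out
  }
  accg <- 0
  for (i in 1:m) {
    a <- gmag(unclass(ref[[i]])[, , ctr]); b <- gmag(unclass(tst[[i]])[, , ctr])
    accg <- accg + sqrt(sum((a - b)^2) / 64)
  }
  expect_equal(grmse_mean(ref, tst)$mean, accg / m, tolerance = 1e-12)

  # permutation invariance of the summary over the volume set
  perm <- c(2, 3, 1)
  expect_equal(mse_mean(ref[perm], tst[perm])$mean, mse_mean(ref, tst)$mean)
})

test_that("CNR matches the worked example and a brute-force ROI oracle", {
  expect_equal(ns$cnr_of(c(2, 2), c(0, 2)), sqrt(2))
  expect_equal(ns$cnr_of(c(1, 1), c(0, 2)), 0)  # u_f = u_b

  set.seed(3)
  n <- 40
  vol <- make_vol(array(rnorm(n * n * 5, 0.06, 0.01), c(n, n, 5)), voxel = 0.2)
  got <- cnr_mean(list(vol), c(0, 0, 0), diameter = 2, annulus = c(1.25, 2))
  # oracle: recompute masks and Eq 9 from scratch
  sl <- unclass(vol)[, , 3]
  coords <- (seq_len(n) - (n + 1) / 2) * 0.2
  r2 <- outer(coords^2, coords^2, `+`)
  fg <- sl[r2 <= 1]; bg <- sl[r2 > 1.25^2 & r2 <= 2^2]
  pv <- function(x) mean((x - mean(x))^2)
  want <- abs(mean(fg) - mean(bg)) / sqrt((pv(fg) + pv(bg)) / 2)
  expect_equal(got$mean, want, tolerance = 1e-12)

  expect_error(cnr_mean(list(vol), c(0, 0, 0), diameter = 30), "ROI")
})

test_that("frequency responses localize constants at DC and difference to zero", {
  cst <- make_vol(array(2, c(8, 8, 8)))
  fr <- frequency_response(list(cst))
  ctr <- c(5, 5)  # fftshifted DC bin
  spec <- 10^fr$spectrum
  expect_gt(spec[ctr[1], ctr[2]], 100)
  expect_lt(max(spec[-(ctr[1] + 8 * (ctr[2] - 1))]), 1e-8)

  set.seed(4)
  vols <- lapply(1:3, function(i) make_vol(array(rnorm(512), c(8, 8, 8))))
  ra <- frequency_response(vols, "coronal")
  rb <- frequency_response(vols, "coronal")
  expect_equal(frequency_mse(ra, rb), 0)
  expect_length(ra$profile, 8)
  rc <- frequency_response(lapply(1:3, function(i)
    make_vol(array(rnorm(4 * 4 * 4), c(4, 4, 4)))), "coronal")
  expect_error(frequency_mse(ra, rc), "shape")
})

test_that("improvement report reproduces the published arithmetic", {
  base <- c(mse = 41.09, cnr = 1.14)
  meth <- c(mse = 7.09, cnr = 3.24)
  out <- improvement_report(base, meth)
  expect_equal(round(out[["mse"]], 1), 82.7)   # decrease in percent
  expect_equal(round(out[["cnr"]], 1), 184.2)  # increase in percent
  expect_equal(improvement_report(base, base), c(mse = 0, cnr = 0))
  expect_true(is.na(improvement_report(c(mse = 0), c(mse = 1))[["mse"]]))
})
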