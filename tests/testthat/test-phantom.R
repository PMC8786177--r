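test_that("power-law field obeys the DC rule and is seeded-deterministic", {
  f1 <- generate_power_law_field(16, 1.5, seed = 3)
  f2 <- generate_power_law_field(16, 1.5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, generate_power_law_field(16, 1.5, seed = 4)))
  expect_true(all(is.finite(f1)))
  expect_error(generate_power_law_field(3, 1.5), "side")
  expect_error(generate_power_law_field(16, -1), "exponent")

  # exponent 0: flat filter except DC (doubled); spectrum ratio to the white
  # input must be exactly the filter
  set.seed(5)
  z <- array(rnorm(16^3), dim = rep(16, 3))
  f0 <- generate_power_law_field(16, 0, seed = 5)
  ratio <- fft(f0) / fft(z)
  expect_equal(Re(ratio[1, 1, 1]), 2, tolerance = 1e-10)  # DC rule at exponent 0
  expect_equal(Re(ratio[5, 3, 2]), 1, tolerance = 1e-10)
})

radial_power_slope <- function(side, exponent, seed) {
  f <- generate_power_law_field(side, exponent, seed)
  p <- abs(stats::fft(f))^2
  fr <- dbtdeblur:::fft_freqs(side)
  r <- sqrt(outer(outer(fr^2, fr^2, `+`), fr^2, `+`))
  sel <- r > 0.05 & r < 0.35
  unname(stats::coef(stats::lm(log(p[sel]) ~ log(r[sel])))[2])
}

test_that("amplitude exponent 1.5 gives a mid-band power-spectrum slope near -3", {
  slopes <- vapply(1:5, function(s) radial_power_slope(64, 1.5, s), 0)
  expect_lt(abs(mean(slopes) + 3), 0.3)
  flat <- vapply(1:3, function(s) radial_power_slope(64, 0, s), 0)
  expect_lt(abs(mean(flat)), 0.3)
})

test_that("VGF thresholding matches the brute-force sort oracle", {
  # integers 1..27 on a 3^3 grid: round(0.3 * 27) = 8 largest -> glandular
  field <- array(as.numeric(1:27), dim = c(3, 3, 3))
  mask <- array(TRUE, dim = c(3, 3, 3))
  out <- apply_vgf(field, mask, 0.3, mu_gland = 1, mu_adipose = 0)
  expect_identical(which(out == 1), which(field >= 20))
  expect_equal(sum(out == 1), 8)

  # vgf = 1: everything glandular
  all_g <- apply_vgf(field, mask, 1, mu_gland = 7, mu_adipose = 0)
  expect_true(all(all_g == 7))

  # exact count invariant on random fields, against an independent sort oracle
  set.seed(9)
  for (vgf in c(0.15, 0.3, 0.5)) {
    fld <- array(rnorm(6^3), dim = c(6, 6, 6))
    msk <- array(runif(6^3) > 0.3, dim = c(6, 6, 6))
    res <- apply_vgf(fld, msk, vgf, 1, 0)
    n <- sum(msk)
    expect_equal(sum(res[msk] == 1), floor(vgf * n + 0.5))
    # oracle: the glandular voxels are exactly the top-k values
    expect_true(min(fld[msk][res[msk] == 1]) >= max(fld[msk][res[msk] == 0]))
  }
  expect_error(apply_vgf(field, mask, 0), "vgf")
  expect_error(apply_vgf(field, mask, 1.2), "vgf")
  expect_error(apply_vgf(field, array(FALSE, c(3, 3, 3)), 0.5), "mask")
})

test_that("breast phantom pipeline is deterministic, binary and near target VGF", {
  p <- phantom_params_small(seed = 21)
  v1 <- generate_breast_phantom(p)
  v2 <- generate_breast_phantom(p)
  expect_identical(unclass(v1), unclass(v2))
  expect_identical(dim(v1), p$crop_shape)
  expect_setequal(unique(as.numeric(v1)), c(p$mu_adipose, p$mu_gland))

  # realized crop VGF fluctuates around the target (threshold is set on the
  # sphere, crop is a correlated sub-volume)
  fr <- vapply(1:10, function(s)
    mean(generate_breast_phantom(phantom_params_small(seed = s)) ==
           p$mu_gland), 0)
  expect_lt(abs(mean(fr) - 0.30), 0.08)

  expect_error(phantom_params(crop_shape = c(500, 500, 100)),
               "sphere bounding box")
  expect_error(phantom_params(vgf = 0), "vgf")
})

test_that("lesion insertion follows voxel-center inclusion", {
  n <- 60L
  vol <- attenuation_volume(array(0.0456, c(n, n, n)), 0.105)
  # 4 mm lesion at 0.105 mm voxels: analytic sphere volume oracle within 2%
  les <- insert_lesion(vol, c(0, 0, 0), 4, 0.0844)
  count <- sum(les == 0.0844)
  expect_lt(abs(count - 4 / 3 * pi * (2 / 0.105)^3) /
              (4 / 3 * pi * (2 / 0.105)^3), 0.02)
  # untouched voxels keep their value; at most three distinct values overall
  expect_setequal(unique(as.numeric(les)), c(0.0456, 0.0844))

  expect_identical(insert_lesion(vol, c(0, 0, 0), 0), vol)
  expect_error(insert_lesion(vol, c(3, 0, 0), 4), "outside")

  # on a phantom: at most three values after insertion
  ph <- generate_breast_phantom(phantom_params_small(seed = 2))
  ph2 <- insert_lesion(ph, c(0, 0, 0), 1.0)
  expect_lte(length(unique(as.numeric(ph2))), 3L)
})
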