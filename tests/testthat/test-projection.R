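test_that("geometry construction matches the scan protocols", {
  dbt <- make_geometry("dbt")
  expect_length(dbt$angles, 41L)
  expect_equal(range(dbt$angles), c(-20, 20))
  expect_equal(unique(round(diff(dbt$angles), 12)), 1)

  cbct <- make_geometry("cbct")
  expect_length(cbct$angles, 360L)
  expect_equal(unique(round(diff(cbct$angles), 12)), 1)

  wide <- make_geometry("dbt", override_angle_range = 40)
  expect_length(wide$angles, 81L)
  expect_equal(range(wide$angles), c(-40, 40))

  expect_equal(dbt$source_to_iso, 545)
  expect_equal(dbt$detector_to_iso, 105)
  expect_equal(dbt$detector_shape, c(450L, 450L))
  expect_equal(dbt$cell_size, c(0.125, 0.125))

  expect_error(make_geometry("dbt", override_angle_range = 0), "angle range")

  # magnification maps the 56.25 mm detector to ~47.16 mm at the isocenter,
  # consistent with the quoted 47.2 mm field of view
  fov <- 450 * 0.125 * 545 / (545 + 105)
  expect_equal(fov, 47.16, tolerance = 1e-3)
})

test_that("central ray of a uniform cube matches the analytic chord", {
  side <- 32L; mu <- 0.05; vx <- 0.5
  vol <- attenuation_volume(array(mu, c(side, side, side)), vx)
  g <- make_geometry("dbt", n_views = 1L, override_angle_range = 1,
                     detector_shape = c(65L, 65L), cell_size = c(0.25, 0.25))
  g$angles <- 0
  st <- siddon_project(vol, g)
  expect_equal(st$line_integrals[33, 33, 1], mu * side * vx / 10,
               tolerance = 1e-6)
})

test_that("single-voxel integrals match a dense ray-marching oracle", {
  n <- 16L; vx <- 0.5
  arr <- array(0, c(n, n, n)); arr[5, 9, 11] <- 1
  vol <- attenuation_volume(arr, vx)
  g <- small_geometry("dbt")
  st <- siddon_project(vol, g)

  march <- function(ia, iu, iv) {
    beta <- g$angles[ia] * pi / 180
    s <- c(g$source_to_iso * sin(beta), 0, g$source_to_iso * cos(beta))
    u <- (iu - (64 + 1) / 2) * g$cell_size[1]
    v <- (iv - (64 + 1) / 2) * g$cell_size[2]
    p <- c(-g$detector_to_iso * sin(beta) + u * cos(beta), v,
           -g$detector_to_iso * cos(beta) - u * sin(beta))
    # sample only a parameter window bracketing the volume (the voxel sits
    # within ~8 mm of the isocenter at t ~ 0.84 along the ray)
    tt <- seq(0.8, 0.88, length.out = 2e6)
    pts <- cbind(s[1] + tt * (p[1] - s[1]), s[2] + tt * (p[2] - s[2]),
                 s[3] + tt * (p[3] - s[3]))
    idx <- floor(sweep(pts, 2, c(-n * vx / 2, -n * vx / 2, -n * vx / 2)) / vx) + 1
    inside <- idx[, 1] == 5 & idx[, 2] == 9 & idx[, 3] == 11
    sum(inside) / length(tt) * 0.08 * sqrt(sum((p - s)^2)) / 10
  }

  hits <- which(st$line_integrals > 0.5 * max(st$line_integrals), arr.ind = TRUE)
  pick <- hits[c(1, nrow(hits) %/% 2, nrow(hits)), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    got <- st$line_integrals[pick[r, 1], pick[r, 2], pick[r, 3]]
    want <- march(pick[r, 3], pick[r, 1], pick[r, 2])
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("projection is linear and mirror-symmetric for symmetric phantoms", {
  vol <- tiny_sphere_volume(24)
  g <- small_geometry("dbt", n_views = 5L)
  st <- siddon_project(vol, g)
  st2 <- siddon_project(attenuation_volume(unclass(vol) * 3.5,
                                           dbtdeblur:::voxel_size_of(vol)), g)
  expect_equal(st2$line_integrals, 3.5 * st$line_integrals, tolerance = 1e-14)

  # sphere shifted off-center along the depth axis keeps x-mirror symmetry:
  # views at +theta and -theta are u-mirrored copies of each other
  arr <- array(0, c(24, 24, 24))
  cc <- 12.5
  r2 <- outer(outer((seq_len(24) - cc)^2, (seq_len(24) - cc)^2, `+`),
              (seq_len(24) - cc - 4)^2, `+`)
  arr[r2 <= 36] <- 1
  svol <- attenuation_volume(arr, 0.4)
  gs <- small_geometry("dbt", n_views = 3L)   # angles -20, 0, 20
  ss <- siddon_project(svol, gs)
  pplus <- ss$line_integrals[, , 3]
  pminus <- ss$line_integrals[, , 1]
  expect_equal(pminus, pplus[rev(seq_len(nrow(pplus))), ], tolerance = 1e-10)
})

test_that("forward projector and its transpose satisfy the adjoint identity", {
  set.seed(4)
  vol <- attenuation_volume(array(runif(16^3), c(16, 16, 16)), 0.5)
  g <- small_geometry("dbt", n_views = 7L)
  st <- siddon_project(vol, g)
  q <- array(rnorm(length(st$line_integrals)), dim = dim(st$line_integrals))
  qs <- st; qs$line_integrals <- q
  bp <- dbtdeblur:::siddon_backproject(qs, dim(vol), 0.5)
  lhs <- sum(st$line_integrals * q)
  rhs <- sum(unclass(vol) * bp)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
})

test_that("Poisson noise is seeded, unbiased at high flux, with delta-method variance", {
  g <- small_geometry("dbt", n_views = 2L)
  p <- array(1, c(64, 64, 2))
  st <- dbtdeblur:::new_projection_stack(p, g)

  n1 <- add_poisson_noise(st, 1e4, seed = 7)
  n2 <- add_poisson_noise(st, 1e4, seed = 7)
  expect_identical(n1$line_integrals, n2$line_integrals)
  expect_false(identical(n1$line_integrals,
                         add_poisson_noise(st, 1e4, seed = 8)$line_integrals))
  # views draw from independent substreams
  expect_false(identical(n1$line_integrals[, , 1], n1$line_integrals[, , 2]))

  # delta method: var(log(I0/N)) ~ 1/(I0 exp(-p)) at p = 1
  v <- var(as.numeric(n1$line_integrals))
  expect_lt(abs(v - 1 / (1e4 * exp(-1))) / (1 / (1e4 * exp(-1))), 0.1)

  # no-attenuation, high-flux limit: noisy integrals collapse to zero
  st0 <- dbtdeblur:::new_projection_stack(array(0, c(64, 64, 2)), g)
  n0 <- add_poisson_noise(st0, 1e8, seed = 1)
  expect_lt(mean(abs(n0$line_integrals)), 1e-3)

  # default flux divides the total budget across views
  nd <- add_poisson_noise(st, seed = 1)
  expect_equal(nd$photons_per_view, 2e5 / 2)
  expect_error(add_poisson_noise(st, -5), "photons")
})
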