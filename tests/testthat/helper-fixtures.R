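# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# reduced-scale simulated DBT/CBCT pairs at the desk profile (30% VGF, noisy)
desk_cases <- function(n, vgf = 0.30, lesions = NULL, seed = 11L) {
  key <- sprintf("cases_%d_%s_%d_%d", n, format(vgf), length(lesions), seed)
  memo(key, {
    prof <- desk_profile(seed = seed, vgf = vgf)
    lapply(seq_len(n), function(i)
      dbtdeblur:::simulate_profile_case(prof, i, lesions = lesions))
  })
}

# the full two-phase desk pipeline run shared by the acceptance tests
desk_pipeline <- function() {
  memo("pipeline", run_two_phase_pipeline(desk_profile(seed = 1), n_eval_extra = 3L))
}

# fast phantom for projector/reconstruction property tests: binary sphere
tiny_sphere_volume <- function(n = 32L, voxel = 0.4, mu = 0.0802,
                               radius_vox = n / 3) {
  cc <- (n + 1) / 2
  r2 <- outer(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, `+`),
              (seq_len(n) - cc)^2, `+`)
  arr <- array(0, c(n, n, n))
  arr[r2 <= radius_vox^2] <- mu
  attenuation_volume(arr, voxel)
}

small_geometry <- function(mode = "dbt", n_views = NULL, ...) {
  make_geometry(mode, n_views = n_views,
                detector_shape = c(64L, 64L), cell_size = c(0.9, 0.9), ...)
}
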