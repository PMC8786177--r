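# Paired DBT/CBCT simulation and end-to-end pipeline drivers.

#' Simulate one paired DBT/CBCT case
#'
#' Generates a breast phantom, forward-projects it under the DBT and CBCT
#' geometries, adds Poisson noise at the matched total flux (unless
#' `noiseless`), and reconstructs both with FDK on the phantom grid, so
#' voxelwise metrics are well defined.
#'
#' @param params a [phantom_params()]; its `seed` drives the phantom.
#' @param dbt_geometry,cbct_geometry [make_geometry()] objects.
#' @param total_photons incident photons per detector cell summed over views
#'   (split as `total_photons / n_views` per view); ignored when
#'   `photons_per_view` is given.
#' @param photons_per_view incident photons per detector cell per view, the
#'   same for both modalities. The scale profiles use `2e5` here: the
#'   published image-quality results require this flux, whereas the split
#'   total-flux convention leaves the reference reconstruction
#'   noise-dominated (see the methods vignette).
#' @param noise add Poisson noise (default TRUE).
#' @param noise_seed base seed for the noise; DBT and CBCT use independent
#'   substreams derived from it.
#' @param lesions optional list of `list(center =, diameter =)` lesions
#'   inserted after the VGF step.
#' @return List with `$phantom`, `$dbt`, `$cbct` volumes.
#' @export
simulate_case <- function(params,
                          dbt_geometry = make_geometry("dbt"),
                          cbct_geometry = make_geometry("cbct"),
                          total_photons = 2e5, photons_per_view = NULL,
                          noise = TRUE,
                          noise_seed = params$seed, lesions = NULL) {
  ph <- generate_breast_phantom(params)
  if (!is.null(lesions))
    for (le in lesions)
      ph <- insert_lesion(ph, le$center, le$diameter, params$mu_lesion)
  grid <- dim(ph)
  vs <- voxel_size_of(ph)

  run <- function(geom, sub_seed) {
    stack <- siddon_project(ph, geom)
    if (noise) {
      i0 <- photons_per_view %||% (total_photons / length(geom$angles))
      stack <- add_poisson_noise(stack, i0, seed = sub_seed)
    }
    fdk_reconstruct(stack, grid, vs)
  }
  list(phantom = ph,
       dbt = run(dbt_geometry, 2L * as.integer(noise_seed) + 1L),
       cbct = run(cbct_geometry, 2L * as.integer(noise_seed) + 2L))
}

#' Scale profiles for the simulation + training pipeline
#'
#' `paper_profile()` carries the full-scale study conditions (899^3 noise
#' cubes, 288 x 288 x 144 volumes, 450^2 detector, 48^3 patches, 10-block /
#' 40-filter Phase 1, 32-filter 4-level U-Net, 100 epochs, 100 volume pairs).
#' `desk_profile()` is the reduced configuration used for continuous testing:
#' identical pipeline logic on 64 x 64 x 48 volumes (128^3 noise cubes,
#' 120-voxel sphere), a 128 x 96 detector at the same cell pitch, 16^3
#' patches, a 3-block / 16-filter Phase 1, an 8-filter 3-level U-Net (its
#' 68-pixel receptive field covers the reduced-scale coronal PSF, mirroring
#' the full-scale design rule) and a short Adam schedule. Both profiles use
#' 2e5 incident photons per detector cell per view (see the methods
#' vignette for the flux-convention discussion).
#'
#' @param seed base seed.
#' @param vgf volumetric glandular fraction of the training condition.
#' @return A named list of constructors and sizes consumed by
#'   [run_two_phase_pipeline()].
#' @export
paper_profile <- function(seed = 1L, vgf = 0.30) {
  list(name = "paper",
       phantom = function(s) phantom_params(vgf = vgf, seed = s),
       dbt_geometry = make_geometry("dbt"),
       cbct_geometry = make_geometry("cbct"),
       patch_side = 48L,
       phase1 = phase1_spec(n_blocks = 10L, n_filters = 40L, seed = seed),
       phase2 = phase2_spec(base_filters = 32L, pooling_levels = 4L, seed = seed),
       cfg = train_config(epochs = 100L, seed = seed),
       n_pairs = 100L,
       photons_per_view = 2e5,
       seed = as.integer(seed))
}

#' @rdname paper_profile
#' @export
desk_profile <- function(seed = 1L, vgf = 0.30) {
  list(name = "desk",
       phantom = function(s) phantom_params_small(crop_shape = c(64L, 64L, 48L),
                                                  vgf = vgf, seed = s),
       dbt_geometry = make_geometry("dbt", detector_shape = c(128L, 96L)),
       cbct_geometry = make_geometry("cbct", detector_shape = c(128L, 96L)),
       patch_side = 16L,
       phase1 = phase1_spec(n_blocks = 3L, n_filters = 16L, seed = seed),
       phase2 = phase2_spec(base_filters = 8L, pooling_levels = 3L, seed = seed),
       cfg = train_config(epochs = 10L, seed = seed),
       n_pairs = 10L,
       photons_per_view = 2e5,
       seed = as.integer(seed))
}

# simulate the i-th pair of a profile (deterministic in profile seed and i)
simulate_profile_case <- function(profile, i, vgf = NULL, lesions = NULL,
                                  noise = TRUE) {
  par_fun <- profile$phantom
  params <- par_fun(profile$seed * 1000L + i)
  if (!is.null(vgf)) {
    params$vgf <- vgf
    params <- do.call(phantom_params, params)
  }
  simulate_case(params, profile$dbt_geometry, profile$cbct_geometry,
                photons_per_view = profile$photons_per_view, noise = noise,
                noise_seed = profile$seed * 1000L + i, lesions = lesions)
}

#' Run the full two-phase pipeline at a given scale profile
#'
#' Simulates `n_pairs` DBT/CBCT pairs, splits them 1:1:3 (then 1:1:1),
#' trains Phase 1 (MAE) on patches, aggregates and slices, trains Phase 2
#' with the requested loss, and deblurs the held-out evaluation volumes
#' (the Phase-2 test set plus `n_eval_extra` freshly simulated pairs unseen
#' by either phase).
#'
#' @param profile a [desk_profile()] / [paper_profile()] list.
#' @param loss_kind Phase-2 objective (`"mae"`, `"al-mae"`, `"pl-mae"`).
#' @param loss_cfg a [loss_config()] (needed for the non-MAE objectives).
#' @param n_eval_extra extra held-out pairs for evaluation.
#' @param verbose print progress.
#' @return List with the simulations, split, trained models, evaluation
#'   pairs and their deblurred volumes.
#' @export
run_two_phase_pipeline <- function(profile = desk_profile(),
                                   loss_kind = "mae",
                                   loss_cfg = loss_config(),
                                   n_eval_extra = 3L, verbose = FALSE) {
  n <- profile$n_pairs
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d volume pairs", n)
  pairs <- lapply(seq_len(n), function(i) simulate_profile_case(profile, i))
  split <- split_dataset(n, profile$seed)

  say("training phase 1")
  tr_patches <- concat_patch_sets(lapply(split$phase1$train, function(i)
    extract_patches(pairs[[i]], profile$patch_side)))
  val_patches <- concat_patch_sets(lapply(split$phase1$val, function(i)
    extract_patches(pairs[[i]], profile$patch_side)))
  g1 <- train_phase1(tr_patches, profile$cfg, profile$phase1,
                     val_patches = val_patches, verbose = verbose)

  say("aggregating phase-1 outputs")
  sl_train <- aggregate_and_slice(g1, pairs[split$phase2$train])
  sl_val <- aggregate_and_slice(g1, pairs[split$phase2$val])

  say("training phase 2 (%s)", loss_kind)
  g2 <- train_phase2(sl_train, profile$cfg, loss_kind, profile$phase2,
                     loss_cfg, val_slices = sl_val, verbose = verbose)

  say("evaluating on held-out volumes")
  eval_pairs <- c(pairs[split$phase2$test],
                  lapply(seq_len(n_eval_extra), function(j)
                    simulate_profile_case(profile, n + j)))
  deblurred <- lapply(eval_pairs, function(pr) infer(pr$dbt, g1, g2))
  phase1_out <- lapply(eval_pairs, function(pr) {
    out <- denorm_window(apply_phase1_norm(g1, norm_window(unclass(pr$dbt))))
    attenuation_volume(out, voxel_size_of(pr$dbt))
  })

  list(profile = profile, pairs = pairs, split = split, g1 = g1, g2 = g2,
       eval_pairs = eval_pairs, phase1_out = phase1_out, deblurred = deblurred)
}
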