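#' Cone-beam scan geometry
#'
#' A rotating source/flat-detector orbit shared by the DBT and CBCT modes:
#' the two differ only in angular range and view count. The rotation axis is
#' y (the second volume axis); at gantry angle 0 the source sits on +z, so the
#' axial (in-focus) plane is x-y, the depth axis is z, and the coronal plane
#' is x-z.
#'
#' @param mode `"dbt"` (41 views, -20..20 deg) or `"cbct"` (360 views,
#'   -180..180 deg).
#' @param override_angle_range half-range in degrees (symmetric about 0) to
#'   replace the default limited-angle arc, e.g. 40 for a -40..40 deg scan.
#' @param n_views number of views; defaults to the mode's standard count, or
#'   to `2 * override_angle_range + 1` (1 deg spacing) when a range override
#'   is given.
#' @param source_to_iso,detector_to_iso distances in mm.
#' @param detector_shape detector cell counts (u, v).
#' @param cell_size detector cell pitch in mm (u, v).
#' @return A `scan_geometry` object.
#' @export
make_geometry <- function(mode = c("dbt", "cbct"),
                          override_angle_range = NULL,
                          n_views = NULL,
                          source_to_iso = 545,
                          detector_to_iso = 105,
                          detector_shape = c(450L, 450L),
                          cell_size = c(0.125, 0.125)) {
  mode <- match.arg(mode)
  if (source_to_iso <= 0) stop("source_to_iso must be positive")
  if (mode == "dbt") {
    half <- override_angle_range %||% 20
    if (half <= 0) stop("empty angle range")
    nv <- n_views %||% (2L * as.integer(half) + 1L)
    angles <- seq(-half, half, length.out = nv)
  } else {
    if (!is.null(override_angle_range))
      stop("angle range override applies to the limited-angle (dbt) mode")
    nv <- n_views %||% 360L
    step <- 360 / nv
    angles <- seq(-180, by = step, length.out = nv)
  }
  if (length(angles) < 1 || any(diff(angles) <= 0))
    stop("angles must be non-empty and strictly increasing")
  structure(list(mode = mode,
                 source_to_iso = source_to_iso,
                 detector_to_iso = detector_to_iso,
                 angles = angles,
                 detector_shape = as.integer(detector_shape),
                 cell_size = as.numeric(cell_size),
                 rotation_axis = "y"),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s: %d views, %.1f..%.1f deg, SID %.0f mm, DID %.0f mm\n",
              toupper(x$mode), length(x$angles), min(x$angles), max(x$angles),
              x$source_to_iso, x$detector_to_iso))
  cat(sprintf("  detector %d x %d cells @ %.3g x %.3g mm\n",
              x$detector_shape[1], x$detector_shape[2],
              x$cell_size[1], x$cell_size[2]))
  invisible(x)
}

# angular spacing used as the backprojection weight (uniform grids only)
view_spacing <- function(geometry) {
  a <- geometry$angles
  if (length(a) == 1) return(pi / 180)
  mean(diff(a)) * pi / 180
}

new_projection_stack <- function(line_integrals, geometry,
                                 photons_per_view = "noiseless",
                                 noise_seed = NULL) {
  structure(list(line_integrals = line_integrals, geometry = geometry,
                 photons_per_view = photons_per_view, noise_seed = noise_seed),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$line_integrals)
  noise <- if (identical(x$photons_per_view, "noiseless")) "noiseless"
           else sprintf("%.3g photons/view", x$photons_per_view)
  cat(sprintf("<projection_stack> %d x %d x %d (%s, %s)\n",
              d[1], d[2], d[3], toupper(x$geometry$mode), noise))
  invisible(x)
}

#' Forward-project a volume with Siddon ray tracing
#'
#' Computes, for every view and detector cell, the exact line integral of
#' attenuation along the source-to-cell ray using voxel intersection lengths
#' (Siddon's algorithm). Rays that miss the volume yield 0.
#'
#' @param volume an [attenuation_volume()] centered at the isocenter.
#' @param geometry a [make_geometry()] object.
#' @return A `projection_stack` of dimensionless line integrals (cm^-1 x cm).
#' @export
siddon_project <- function(volume, geometry) {
  stopifnot(inherits(volume, "attenuation_volume"),
            inherits(geometry, "scan_geometry"))
  vs <- voxel_size_of(volume)
  if (any(vs <= 0)) stop("degenerate voxel size")
  proj <- cpp_siddon_project(as.numeric(volume), dim(volume), vs,
                             origin_of(volume),
                             geometry$angles * pi / 180,
                             geometry$source_to_iso,
                             geometry$detector_to_iso,
                             geometry$detector_shape[1],
                             geometry$detector_shape[2],
                             geometry$cell_size[1], geometry$cell_size[2])
  new_projection_stack(proj, geometry)
}

# exact adjoint of siddon_project (test/diagnostic use)
siddon_backproject <- function(stack, grid, voxel_size, origin = c(0, 0, 0)) {
  g <- stack$geometry
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  vol <- cpp_siddon_backproject(as.numeric(stack$line_integrals),
                                as.integer(grid), voxel_size, origin,
                                g$angles * pi / 180, g$source_to_iso,
                                g$detector_to_iso,
                                g$detector_shape[1], g$detector_shape[2],
                                g$cell_size[1], g$cell_size[2])
  array(vol, dim = grid)
}

#' Add Poisson counting noise to a projection stack
#'
#' Each cell's expected transmitted count is `lambda = I0 * exp(-p)`; a
#' Poisson draw N replaces the line integral with `log(I0 / max(N, 1))` (the
#' max guards the log against zero counts). The default flux matches the
#' total-dose convention `2e5 / n_views` incident photons per cell per view,
#' and every view draws from an independent substream derived from
#' `(seed, view index)`.
#'
#' @param stack a noiseless `projection_stack`.
#' @param photons_per_view incident photons per detector cell per view;
#'   default `2e5 / n_views`.
#' @param seed integer seed.
#' @export
add_poisson_noise <- function(stack, photons_per_view = NULL, seed = 1L) {
  stopifnot(inherits(stack, "projection_stack"))
  n_views <- length(stack$geometry$angles)
  i0 <- photons_per_view %||% (2e5 / n_views)
  if (i0 <= 0) stop("photons_per_view must be positive")
  p <- stack$line_integrals
  out <- p
  for (ia in seq_len(n_views)) {
    set.seed((as.integer(seed) %% 1000003L) * 2048L + ia)
    lam <- i0 * exp(-p[, , ia])
    n <- stats::rpois(length(lam), lam)
    out[, , ia] <- log(i0 / pmax(n, 1))
  }
  new_projection_stack(out, stack$geometry, i0, as.integer(seed))
}
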