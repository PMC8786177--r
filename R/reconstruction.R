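#' Hanning-weighted ramp filter weights
#'
#' Discrete frequency response `|nu| * W(nu)` on the FFT grid of length `n`,
#' where `W` is a Hanning window equal to 1 at DC and 0 at the Nyquist
#' frequency. Frequencies are in cycles per unit of `cell_pitch`, so filtering
#' a projection sampled at pitch `du` (cm) yields values on the cm^-1
#' attenuation scale after backprojection.
#'
#' @param n_cells FFT length (>= 2); callers zero-pad rows to at least twice
#'   the detector width before filtering to avoid circular convolution.
#' @param cell_pitch sample pitch (length unit defines the output scale).
#' @return Numeric vector of `n_cells` non-negative frequency weights.
#' @export
ramp_hanning_filter <- function(n_cells, cell_pitch) {
  if (n_cells < 2) stop("n_cells must be >= 2")
  if (cell_pitch <= 0) stop("cell_pitch must be positive")
  f <- abs(fft_freqs(n_cells)) / cell_pitch      # cycles per length unit
  f_nyq <- 1 / (2 * cell_pitch)
  f * 0.5 * (1 + cos(pi * f / f_nyq))
}

# filter projection rows (along u) with the ramp-Hanning kernel via
# zero-padded FFT; P is nu x nv
filter_rows <- function(p, du, n_pad) {
  h <- ramp_hanning_filter(n_pad, du)
  pad <- matrix(0, n_pad, ncol(p))
  pad[seq_len(nrow(p)), ] <- p
  q <- Re(stats::mvfft(stats::mvfft(pad) * h, inverse = TRUE)) / n_pad
  q[seq_len(nrow(p)), , drop = FALSE]
}

#' FDK cone-beam reconstruction
#'
#' Standard Feldkamp-Davis-Kress filtered backprojection for a circular
#' flat-panel orbit: cosine pre-weighting, row-wise ramp-Hanning filtering on
#' a >= 2x zero-padded grid, then distance-weighted voxel-driven
#' backprojection with bilinear detector interpolation. Views are weighted by
#' their angular spacing over the acquired arc (no 2*pi renormalization), so a
#' full-angle CBCT scan approximates the attenuation map and a limited-angle
#' DBT scan is its missing-cone counterpart on the same scale.
#'
#' @param stack a `projection_stack`.
#' @param grid reconstruction grid (voxel triple).
#' @param voxel_size voxel pitch in mm (scalar or length 3).
#' @param origin grid center in mm (default isocenter).
#' @return A `recon_volume` (an [attenuation_volume()] with provenance).
#' @export
fdk_reconstruct <- function(stack, grid = c(288L, 288L, 144L),
                            voxel_size = 0.105, origin = c(0, 0, 0)) {
  stopifnot(inherits(stack, "projection_stack"))
  g <- stack$geometry
  proj <- stack$line_integrals
  nu <- g$detector_shape[1]; nv <- g$detector_shape[2]
  if (!all(dim(proj) == c(nu, nv, length(g$angles))))
    stop("projection stack inconsistent with its geometry")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)

  sid <- g$source_to_iso
  sdd <- g$source_to_iso + g$detector_to_iso
  du <- g$cell_size[1] * sid / sdd          # virtual detector through origin
  dv <- g$cell_size[2] * sid / sdd
  u <- (seq_len(nu) - (nu + 1) / 2) * du
  v <- (seq_len(nv) - (nv + 1) / 2) * dv
  cosw <- sid / sqrt(sid^2 + outer(u^2, v^2, `+`))

  n_pad <- 2^ceiling(log2(2 * nu))
  dbeta <- view_spacing(g)
  filt <- array(0, dim = dim(proj))
  for (ia in seq_along(g$angles)) {
    # du in cm so the backprojected values land on the cm^-1 scale
    filt[, , ia] <- filter_rows(proj[, , ia] * cosw, du / 10, n_pad) *
      (0.5 * dbeta)
  }
  vol <- cpp_fdk_backproject(as.numeric(filt), nu, nv, du, dv,
                             g$angles * pi / 180, sid,
                             as.integer(grid), voxel_size, origin)
  out <- attenuation_volume(array(vol, dim = grid), voxel_size, origin)
  attr(out, "provenance") <- list(mode = g$mode, n_views = length(g$angles),
                                  angle_range = range(g$angles))
  class(out) <- c("recon_volume", class(out))
  out
}

#' Measure the reconstructed point spread function
#'
#' Places a unit impulse voxel at the isocenter of an otherwise empty volume,
#' projects it noiselessly through the given geometry, reconstructs with FDK
#' at the requested voxel pitch, and measures the connected extent of |PSF|
#' above `threshold_fraction` of its peak: along the depth (z) axis in the
#' central coronal plane, and along x in the axial plane through the peak.
#'
#' @param geometry a [make_geometry()] object.
#' @param grid reconstruction grid; the default is narrow laterally and long
#'   along depth to capture the limited-angle elongation.
#' @param voxel_size reconstruction voxel pitch in mm.
#' @param threshold_fraction fraction of the peak magnitude defining the
#'   extent (default 0.05).
#' @return A `psf_estimate` with the reconstructed PSF and its extents.
#' @export
measure_psf <- function(geometry, grid = c(33L, 33L, 181L),
                        voxel_size = 0.105, threshold_fraction = 0.05) {
  stopifnot(inherits(geometry, "scan_geometry"),
            threshold_fraction > 0, threshold_fraction < 1)
  grid <- as.integer(grid)
  if (any(grid %% 2L == 0L))
    stop("grid sides must be odd so a voxel center sits exactly at the isocenter")
  src_side <- 17L
  src <- array(0, dim = rep(src_side, 3))
  src[(src_side + 1) / 2, (src_side + 1) / 2, (src_side + 1) / 2] <- 1
  impulse <- attenuation_volume(src, voxel_size)
  stack <- siddon_project(impulse, geometry)
  psf <- fdk_reconstruct(stack, grid, voxel_size)

  a <- abs(psf)
  peak_idx <- arrayInd(which.max(a), dim(a))
  peak <- a[peak_idx]
  if (peak <= 0) stop("degenerate PSF: no energy above zero")
  thr <- threshold_fraction * peak

  depth_profile <- a[peak_idx[1], peak_idx[2], ]   # along z in the coronal plane
  axial_profile <- a[, peak_idx[2], peak_idx[3]]   # along x in the axial plane
  extent_depth <- connected_extent(depth_profile, peak_idx[3], thr)
  extent_axial <- connected_extent(axial_profile, peak_idx[1], thr)
  if (extent_depth < 1 || extent_axial < 1) stop("empty above-threshold set")

  structure(list(values = unclass(psf), voxel_size = voxel_size,
                 threshold_fraction = threshold_fraction,
                 peak = peak, peak_index = peak_idx,
                 extent_axial = extent_axial,
                 extent_coronal_depth = extent_depth,
                 mode = geometry$mode,
                 angle_range = range(geometry$angles)),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf("<psf_estimate> %s %.0f..%.0f deg: depth extent %d px, axial extent %d px (%.0f%% threshold)\n",
              toupper(x$mode), x$angle_range[1], x$angle_range[2],
              x$extent_coronal_depth, x$extent_axial,
              100 * x$threshold_fraction))
  invisible(x)
}

# length of the above-threshold run containing index `center`
connected_extent <- function(profile, center, thr) {
  above <- profile >= thr
  if (!above[center]) return(0L)
  lo <- center
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- center
  while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  hi - lo + 1L
}
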