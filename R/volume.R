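#' Attenuation volume
#'
#' A 3D grid of linear attenuation coefficients (cm^-1) on an isotropic or
#' anisotropic voxel lattice centered on the scanner isocenter. Voxel centers
#' sit at `origin + (i - (n-1)/2) * voxel_size` (0-based index `i`, mm), so the
#' grid center coincides with `origin`.
#'
#' @param values 3D numeric array (cm^-1).
#' @param voxel_size voxel pitch in mm (scalar or length-3).
#' @param origin world position (mm) of the grid center, default isocenter.
#' @return An `attenuation_volume`: the array with voxel-size/origin attributes.
#' @export
attenuation_volume <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0), length(origin) == 3)
  if (!all(is.finite(values))) stop("attenuation values must be finite")
  structure(values,
            voxel_size = as.numeric(voxel_size),
            origin = as.numeric(origin),
            class = c("attenuation_volume", "array"))
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("<attenuation_volume> %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], vs[1]))
  cat(sprintf("  range [%.4g, %.4g] cm^-1\n", min(x), max(x)))
  invisible(x)
}

voxel_size_of <- function(vol) attr(vol, "voxel_size") %||% stop("missing voxel_size")
origin_of <- function(vol) attr(vol, "origin") %||% c(0, 0, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero (base round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# world coordinates of voxel centers along one axis (mm)
axis_coords <- function(n, voxel, origin = 0) origin + (seq_len(n) - (n + 1) / 2) * voxel

# central crop start (1-based), shared by sphere and rectangle extraction
crop_start <- function(n, c) floor((n - c) / 2) + 1L

central_slice_index <- function(n) floor(n / 2) + 1L  # floor(side/2), 0-based rule
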