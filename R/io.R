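# Volume and projection persistence: multi-page 32-bit float TIFF with a YAML
# sidecar carrying voxel size, units and provenance.

#' Write / read a volume as multi-page TIFF + YAML metadata
#'
#' Pages are axial (x-y) planes ordered along z. Values are stored as 32-bit
#' floats in cm^-1; the sidecar (`<path>.yaml`) records voxel size, units and
#' any extra metadata.
#'
#' @param volume an [attenuation_volume()].
#' @param path output TIFF path.
#' @param meta extra metadata list for the sidecar.
#' @export
write_volume <- function(volume, path, meta = list()) {
  stopifnot(inherits(volume, "attenuation_volume"))
  arr <- unclass(volume)
  sc <- tiff_scale(arr)
  pages <- lapply(seq_len(dim(arr)[3]), function(k)
    t((arr[, , k] - sc[1]) / (sc[2] - sc[1])))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(dims = dim(arr), voxel_size_mm = voxel_size_of(volume),
                 origin_mm = origin_of(volume), units = "cm^-1",
                 value_range = sc), meta)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

# TIFF sample values must live in [0, 1]; volumes are stored affinely
# rescaled with the true range recorded in the sidecar
tiff_scale <- function(arr) {
  lo <- min(arr); hi <- max(arr)
  if (hi <= lo) hi <- lo + 1
  c(lo, hi)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  sc <- unlist(meta$value_range)
  arr <- array(0, dim = unlist(meta$dims))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * (sc[2] - sc[1]) + sc[1]
  attenuation_volume(arr, unlist(meta$voxel_size_mm), unlist(meta$origin_mm))
}

#' Write / read a projection stack as multi-page TIFF + YAML metadata
#'
#' One page per view (detector u-v grids); the sidecar stores the geometry.
#' @param stack a `projection_stack`.
#' @param path output TIFF path.
#' @export
write_projections <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  p <- stack$line_integrals
  sc <- tiff_scale(p)
  pages <- lapply(seq_len(dim(p)[3]), function(k)
    t((p[, , k] - sc[1]) / (sc[2] - sc[1])))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  g <- stack$geometry
  yaml::write_yaml(list(dims = dim(p), value_range = sc, mode = g$mode,
                        source_to_iso = g$source_to_iso,
                        detector_to_iso = g$detector_to_iso,
                        angles_deg = g$angles,
                        detector_shape = g$detector_shape,
                        cell_size_mm = g$cell_size,
                        photons_per_view = stack$photons_per_view,
                        noise_seed = stack$noise_seed),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  sc <- unlist(meta$value_range)
  p <- array(0, dim = unlist(meta$dims))
  for (k in seq_along(pages)) p[, , k] <- t(pages[[k]]) * (sc[2] - sc[1]) + sc[1]
  geom <- make_geometry(meta$mode,
                        n_views = length(meta$angles_deg),
                        source_to_iso = meta$source_to_iso,
                        detector_to_iso = meta$detector_to_iso,
                        detector_shape = unlist(meta$detector_shape),
                        cell_size = unlist(meta$cell_size_mm))
  geom$angles <- unlist(meta$angles_deg)
  new_projection_stack(p, geom,
                       photons_per_view = meta$photons_per_view %||% "noiseless",
                       noise_seed = meta$noise_seed)
}
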