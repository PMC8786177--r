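#' Phantom generation parameters
#'
#' Defaults reproduce the anatomical power-law breast phantom used throughout
#' the package: an 899^3 Gaussian noise cube shaped by a 1/f^(3/2) amplitude
#' filter, a central 450-voxel sphere to avoid DFT wrap-around, binary
#' glandular/adipose thresholding at the target volumetric glandular fraction
#' (VGF), and a central 288 x 288 x 144 rectangular crop emulating a
#' compressed breast at 0.105 mm voxels.
#'
#' @param noise_cube_side side of the Gaussian noise cube (voxels).
#' @param sphere_diameter diameter of the central sphere (voxels).
#' @param crop_shape final rectangular volume (voxels, length 3).
#' @param power_exponent amplitude filter exponent (1/f^exponent).
#' @param vgf target volumetric glandular fraction in (0, 1].
#' @param mu_gland,mu_adipose,mu_lesion attenuation coefficients (cm^-1, 20 keV).
#' @param voxel_size voxel pitch in mm.
#' @param seed integer seed; identical parameters give bit-identical phantoms.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(noise_cube_side = 899L,
                           sphere_diameter = 450L,
                           crop_shape = c(288L, 288L, 144L),
                           power_exponent = 1.5,
                           vgf = 0.30,
                           mu_gland = 0.0802,
                           mu_adipose = 0.0456,
                           mu_lesion = 0.0844,
                           voxel_size = 0.105,
                           seed = 1L) {
  if (vgf <= 0 || vgf > 1) stop("vgf must be in (0, 1]")
  if (noise_cube_side < 4) stop("noise_cube_side must be >= 4")
  if (power_exponent < 0) stop("power_exponent must be >= 0")
  if (sphere_diameter > noise_cube_side)
    stop("sphere_diameter larger than the noise cube")
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3 || any(crop_shape < 1)) stop("bad crop_shape")
  if (any(crop_shape > sphere_diameter))
    stop("crop_shape exceeds the sphere bounding box")
  structure(list(noise_cube_side = as.integer(noise_cube_side),
                 sphere_diameter = as.integer(sphere_diameter),
                 crop_shape = crop_shape,
                 power_exponent = power_exponent, vgf = vgf,
                 mu_gland = mu_gland, mu_adipose = mu_adipose,
                 mu_lesion = mu_lesion,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Small-scale phantom parameters
#'
#' A reduced configuration (same pipeline, smaller grids) for fast runs and
#' continuous testing.
#' @param ... overrides passed to [phantom_params()].
#' @export
phantom_params_small <- function(...) {
  defaults <- list(noise_cube_side = 128L, sphere_diameter = 120L,
                   crop_shape = c(64L, 64L, 32L))
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

#' Generate a power-law filtered Gaussian noise field
#'
#' Draws a white Gaussian field, shapes its amplitude spectrum by
#' 1/f^exponent in 3D radial frequency and inverse-transforms back. The
#' zero-frequency filter value is set to twice the filter value of the first
#' non-zero frequency component, which keeps the DC gain finite.
#'
#' @param side cube side in voxels (>= 4).
#' @param exponent amplitude-spectrum exponent (>= 0); 1.5 gives the
#'   anatomical 1/f^3 power-law slope.
#' @param seed integer seed.
#' @return `side^3` numeric array.
#' @export
generate_power_law_field <- function(side, exponent = 1.5, seed = 1L) {
  side <- as.integer(side)
  if (side < 4) stop("side must be >= 4")
  if (exponent < 0) stop("exponent must be >= 0")
  set.seed(seed)
  z <- array(stats::rnorm(side^3), dim = rep(side, 3))
  f1 <- fft_freqs(side)              # cycles per sample along one axis
  fr <- sqrt(outer(outer(f1^2, f1^2, `+`), f1^2, `+`))  # radial frequency
  h <- array(0, dim = dim(fr))
  nz <- fr > 0
  h[nz] <- fr[nz]^(-exponent)
  h[!nz] <- 2 * (min(fr[nz]))^(-exponent)  # DC rule
  out <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / side^3
  out
}

fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Threshold a field to a binary glandular/adipose map at a target VGF
#'
#' Within `mask`, the largest `round(vgf * N)` values (round half away from
#' zero) become glandular tissue and the remainder adipose; ties are broken by
#' flattened array index. Voxels outside the mask are left untouched (the
#' phantom pipeline assigns them adipose).
#'
#' @param field 3D numeric array.
#' @param mask logical array of the same shape, non-empty.
#' @param vgf glandular fraction in (0, 1].
#' @param mu_gland,mu_adipose tissue attenuation coefficients (cm^-1).
#' @return Array of the same shape.
#' @export
apply_vgf <- function(field, mask, vgf, mu_gland = 0.0802, mu_adipose = 0.0456) {
  if (vgf <= 0 || vgf > 1) stop("vgf must be in (0, 1]")
  stopifnot(identical(dim(field), dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  vals <- field[mask]
  n_gland <- round_half_away(vgf * n)
  o <- order(-vals, seq_along(vals))  # descending, stable by flattened index
  out_vals <- rep(mu_adipose, n)
  if (n_gland > 0) out_vals[o[seq_len(min(n_gland, n))]] <- mu_gland
  field[mask] <- out_vals
  field
}

sphere_mask <- function(side) {
  cc <- (side + 1) / 2
  r2 <- outer(outer((seq_len(side) - cc)^2, (seq_len(side) - cc)^2, `+`),
              (seq_len(side) - cc)^2, `+`)
  r2 <= (side / 2)^2
}

central_crop <- function(x, shape) {
  d <- dim(x)
  stopifnot(all(shape <= d))
  s <- mapply(crop_start, d, shape)
  x[s[1]:(s[1] + shape[1] - 1), s[2]:(s[2] + shape[2] - 1),
    s[3]:(s[3] + shape[3] - 1), drop = FALSE]
}

#' Generate a stochastic breast phantom
#'
#' Pipeline: power-law noise cube -> central sphere extraction (wrap-around
#' guard) -> VGF thresholding on the sphere interior -> central rectangular
#' crop. The realized glandular fraction of the crop can deviate slightly from
#' the target because the threshold is set on the sphere, not the crop.
#'
#' @param params a [phantom_params()] object.
#' @return An [attenuation_volume()] containing only the glandular and adipose
#'   attenuation values.
#' @export
generate_breast_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  field <- generate_power_law_field(p$noise_cube_side, p$power_exponent, p$seed)
  box <- central_crop(field, rep(p$sphere_diameter, 3))
  mask <- sphere_mask(p$sphere_diameter)
  box <- apply_vgf(box, mask, p$vgf, p$mu_gland, p$mu_adipose)
  box[!mask] <- p$mu_adipose
  vol <- central_crop(box, p$crop_shape)
  attenuation_volume(vol, p$voxel_size)
}

#' Insert a spherical lesion
#'
#' Voxels whose centers lie within `diameter/2` of `center` are set to
#' `mu_lesion` (voxel-center inclusion, no partial-volume weighting).
#'
#' @param volume an [attenuation_volume()].
#' @param center lesion center in mm (world coordinates; isocenter = 0).
#' @param diameter lesion diameter in mm; 0 leaves the volume unchanged.
#' @param mu_lesion lesion attenuation (cm^-1).
#' @export
insert_lesion <- function(volume, center, diameter, mu_lesion = 0.0844) {
  stopifnot(inherits(volume, "attenuation_volume"), length(center) == 3,
            diameter >= 0)
  if (diameter == 0) return(volume)
  d <- dim(volume); vs <- voxel_size_of(volume); or <- origin_of(volume)
  half <- d * vs / 2
  lo <- or - half; hi <- or + half
  if (any(center - diameter / 2 < lo) || any(center + diameter / 2 > hi))
    stop("lesion extends outside the volume")
  cx <- axis_coords(d[1], vs[1], or[1])
  cy <- axis_coords(d[2], vs[2], or[2])
  cz <- axis_coords(d[3], vs[3], or[3])
  r2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
              (cz - center[3])^2, `+`)
  volume[r2 <= (diameter / 2)^2] <- mu_lesion
  volume
}
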