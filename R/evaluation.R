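# Quantitative evaluation: per-plane MSE / GRMSE / CNR over central slices,
# frequency-domain analysis of the missing cone, and relative-improvement
# reports.

plane_axes <- c(axial = 3L, coronal = 2L, sagittal = 1L)

# central slice of a volume along the given plane's slicing axis
central_slice <- function(vol, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  arr <- unclass(vol)
  ax <- plane_axes[[plane]]
  i <- central_slice_index(dim(arr)[ax])
  switch(plane,
         axial = arr[, , i],
         coronal = arr[, i, ],
         sagittal = arr[i, , ])
}

check_pairs <- function(ref, test) {
  stopifnot(is.list(ref), is.list(test), length(ref) == length(test),
            length(ref) >= 1)
  for (i in seq_along(ref))
    if (!identical(dim(unclass(ref[[i]])), dim(unclass(test[[i]]))))
      stop("shape mismatch between reference and test volumes")
}

summarize_metric <- function(per_volume) {
  list(mean = mean(per_volume),
       sd = if (length(per_volume) > 1) stats::sd(per_volume) else NA_real_,
       per_volume = per_volume)
}

#' Mean 2D MSE over central slices
#'
#' For each volume pair, the mean squared pixel difference of the central
#' slice in the given plane; reported as mean +- sd over volumes.
#'
#' @param ref,test lists of reference / test volumes (same shapes).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @export
mse_mean <- function(ref, test, plane = "axial") {
  check_pairs(ref, test)
  per <- vapply(seq_along(ref), function(i) {
    a <- central_slice(ref[[i]], plane); b <- central_slice(test[[i]], plane)
    mean((a - b)^2)
  }, 0)
  summarize_metric(per)
}

# 2D gradient magnitude, central differences with replicated edges
grad_magnitude <- function(img, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  n1 <- nrow(img); n2 <- ncol(img)
  pad <- img[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  if (operator == "central") {
    gx <- (pad[3:(n1 + 2), 2:(n2 + 1)] - pad[1:n1, 2:(n2 + 1)]) / 2
    gy <- (pad[2:(n1 + 1), 3:(n2 + 2)] - pad[2:(n1 + 1), 1:n2]) / 2
  } else {
    sx <- function(p) p[3:(n1 + 2), ] - p[1:n1, ]
    gx <- (sx(pad)[, 1:n2] + 2 * sx(pad)[, 2:(n2 + 1)] + sx(pad)[, 3:(n2 + 2)]) / 8
    sy <- function(p) p[, 3:(n2 + 2)] - p[, 1:n2]
    gy <- (sy(pad)[1:n1, ] + 2 * sy(pad)[2:(n1 + 1), ] + sy(pad)[3:(n1 + 2), ]) / 8
  }
  sqrt(gx^2 + gy^2)
}

#' Mean 2D GRMSE over central slices
#'
#' Root-mean-squared error between gradient-magnitude images of each central
#' slice pair (per-image root, then averaged over volumes).
#'
#' @inheritParams mse_mean
#' @param operator gradient operator (`"central"` differences with replicated
#'   edges, or `"sobel"`).
#' @export
grmse_mean <- function(ref, test, plane = "axial", operator = "central") {
  check_pairs(ref, test)
  per <- vapply(seq_along(ref), function(i) {
    a <- grad_magnitude(central_slice(ref[[i]], plane), operator)
    b <- grad_magnitude(central_slice(test[[i]], plane), operator)
    sqrt(mean((a - b)^2))
  }, 0)
  summarize_metric(per)
}

#' Mean lesion CNR over central slices
#'
#' Foreground = disk of the lesion's diameter at its center; background =
#' surrounding annulus (defaults 1.25x to 2x the lesion radius).
#' `|u_f - u_b| / sqrt((sigma_f^2 + sigma_b^2) / 2)`, averaged per volume over
#' its lesions, then over volumes.
#'
#' @param volumes list of [attenuation_volume()]s with lesions.
#' @param centers lesion centers: one mm triple, or a list of triples (all
#'   applied to every volume).
#' @param diameter lesion diameter in mm.
#' @param plane evaluation plane (central slice).
#' @param annulus inner/outer background radii as multiples of the lesion
#'   radius.
#' @export
cnr_mean <- function(volumes, centers, diameter, plane = "axial",
                     annulus = c(1.25, 2)) {
  stopifnot(length(volumes) >= 1, diameter > 0)
  if (!is.list(centers)) centers <- list(centers)
  per <- vapply(seq_along(volumes), function(i) {
    vol <- volumes[[i]]
    sl <- central_slice(vol, plane)
    vs <- voxel_size_of(vol); or <- origin_of(vol); d <- dim(vol)
    ax <- plane_axes[[plane]]
    keep <- setdiff(1:3, ax)
    c1 <- axis_coords(d[keep[1]], vs[keep[1]], or[keep[1]])
    c2 <- axis_coords(d[keep[2]], vs[keep[2]], or[keep[2]])
    vals <- vapply(centers, function(ctr) {
      r2 <- outer((c1 - ctr[keep[1]])^2, (c2 - ctr[keep[2]])^2, `+`)
      r <- diameter / 2
      fg <- r2 <= r^2
      bg <- r2 > (annulus[1] * r)^2 & r2 <= (annulus[2] * r)^2
      if (!any(fg) || !any(bg)) stop("lesion ROI outside the image")
      cnr_of(sl[fg], sl[bg])
    }, 0)
    mean(vals)
  }, 0)
  summarize_metric(per)
}

# contrast-to-noise ratio of foreground/background samples
# (population variances: |u_f - u_b| / sqrt((s_f^2 + s_b^2) / 2))
cnr_of <- function(fg, bg) {
  pvar <- function(x) mean((x - mean(x))^2)
  abs(mean(fg) - mean(bg)) / sqrt((pvar(fg) + pvar(bg)) / 2)
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

#' Averaged frequency response of central slices
#'
#' 2D FFT of the central slice of each volume, magnitudes averaged over
#' volumes, displayed on a log10 scale (fftshifted, DC at the center). The
#' central vertical profile runs along the second frequency axis through the
#' zero-frequency column.
#'
#' @param volumes list of volumes.
#' @param plane evaluation plane.
#' @param log_base `"log10"` (default) or `"ln"`.
#' @param average `"spectra"` (average magnitudes, then log; default) or
#'   `"per_image"` (log per image, then average).
#' @return A `frequency_response` with the log spectrum and central profile.
#' @export
frequency_response <- function(volumes, plane = "axial", log_base = c("log10", "ln"),
                               average = c("spectra", "per_image")) {
  log_base <- match.arg(log_base); average <- match.arg(average)
  stopifnot(length(volumes) >= 1)
  lg <- if (log_base == "log10") log10 else log
  mags <- lapply(volumes, function(v) abs(stats::fft(central_slice(v, plane))))
  spec <- if (average == "spectra") lg(Reduce(`+`, mags) / length(mags))
          else Reduce(`+`, lapply(mags, lg)) / length(mags)
  spec <- fftshift2(spec)
  ctr1 <- nrow(spec) %/% 2 + 1  # zero-frequency row after the shift
  structure(list(spectrum = spec, profile = spec[ctr1, ],
                 plane = plane, log_base = log_base, n = length(volumes)),
            class = "frequency_response")
}

#' Frequency-domain MSE between two averaged responses
#'
#' Mean squared difference of the log-scaled averaged magnitude spectra.
#' @param resp_a,resp_b `frequency_response` objects of matching shape.
#' @export
frequency_mse <- function(resp_a, resp_b) {
  if (!identical(dim(resp_a$spectrum), dim(resp_b$spectrum)))
    stop("shape mismatch")
  mean((resp_a$spectrum - resp_b$spectrum)^2)
}

#' Missing-wedge spectral energy of coronal/sagittal slices
#'
#' Mean squared FFT magnitude of central slices inside the double wedge that
#' a +-`half_angle_deg` acquisition leaves unsampled (frequencies steeper
#' than `tan(half_angle)` from the in-plane axis, DC neighborhood excluded).
#' Used to quantify how much of the missing cone a restoration has filled.
#'
#' @param volumes list of volumes.
#' @param plane `"coronal"` (x-z) or `"sagittal"` (y-z).
#' @param half_angle_deg half acquisition angle (20 for the standard scan).
#' @param dc_guard radial bins around DC excluded from the wedge.
#' @export
wedge_energy <- function(volumes, plane = "coronal", half_angle_deg = 20,
                         dc_guard = 2) {
  stopifnot(plane %in% c("coronal", "sagittal"))
  sl <- central_slice(volumes[[1]], plane)
  mask <- wedge_mask(dim(sl), half_angle_deg, dc_guard)
  mean(vapply(volumes, function(v) {
    m <- abs(stats::fft(central_slice(v, plane)))^2
    mean(fftshift2(m)[mask])
  }, 0))
}

wedge_mask <- function(dims, half_angle_deg, dc_guard = 2) {
  f1 <- fftshift_freqs(dims[1])  # in-plane axis
  f2 <- fftshift_freqs(dims[2])  # depth axis
  a1 <- matrix(abs(f1), dims[1], dims[2])
  a2 <- matrix(abs(f2), dims[1], dims[2], byrow = TRUE)
  r <- sqrt(a1^2 + a2^2)
  (a2 > a1 * tan(half_angle_deg * pi / 180)) & (r > dc_guard / dims[1])
}

fftshift_freqs <- function(n) {
  f <- fft_freqs(n)
  f[c((n %/% 2 + 1):n, 1:(n %/% 2))]
}

#' Relative improvement of one metrics set over a baseline
#'
#' Percent decrease for error metrics (MSE, GRMSE, frequency MSE) and percent
#' increase for CNR; `NA` where the baseline is zero.
#'
#' @param baseline,method named numeric vectors or metric summaries (their
#'   `$mean` is used) with matching names.
#' @param higher_is_better names treated as gain metrics (default `"cnr"`).
#' @return Named numeric vector of percent changes.
#' @export
improvement_report <- function(baseline, method, higher_is_better = "cnr") {
  pick <- function(x) vapply(x, function(v) if (is.list(v)) v$mean else as.numeric(v), 0)
  b <- pick(baseline); m <- pick(method)
  stopifnot(identical(names(b), names(m)))
  out <- ifelse(b == 0, NA_real_,
                ifelse(names(b) %in% higher_is_better,
                       100 * (m - b) / b,
                       100 * (b - m) / b))
  names(out) <- names(b)
  out
}

#' Per-plane metrics report for a set of volume pairs
#'
#' Convenience wrapper computing MSE and GRMSE for the requested planes.
#' @param ref,test lists of reference / test volumes.
#' @param planes planes to evaluate.
#' @return A `metrics_report`: nested list `report$plane$metric`.
#' @export
metrics_report <- function(ref, test, planes = c("axial", "coronal", "sagittal")) {
  rep <- lapply(planes, function(pl)
    list(mse = mse_mean(ref, test, pl), grmse = grmse_mean(ref, test, pl)))
  names(rep) <- planes
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (pl in names(x))
    cat(sprintf("  %-9s MSE %.4g +- %.2g   GRMSE %.4g +- %.2g\n", pl,
                x[[pl]]$mse$mean, x[[pl]]$mse$sd,
                x[[pl]]$grmse$mean, x[[pl]]$grmse$sd))
  invisible(x)
}
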