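#' Loss configuration
#'
#' Weights of the Phase-2 objectives: `L_MAE`, `L_MAE + lambda1 * L_AL`
#' (adversarial) and `L_MAE + lambda2 * L_PL` (perceptual), with the WGAN-GP
#' gradient-penalty weight `eta`.
#'
#' @param lambda1 adversarial weight (default 0.001).
#' @param lambda2 perceptual weight (default 0.05).
#' @param eta gradient-penalty weight (default 0.1).
#' @param feature_extractor a [build_feature_extractor()] object, required for
#'   the perceptual loss.
#' @export
loss_config <- function(lambda1 = 0.001, lambda2 = 0.05, eta = 0.1,
                        feature_extractor = NULL) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, eta >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, eta = eta,
                 feature_extractor = feature_extractor),
            class = "loss_config")
}

#' Mean absolute error loss
#'
#' `sum(|pred - target|) / N` with `N` the pixel (2D) or voxel (3D) count of
#' one image; for a batch, average the per-image values.
#' @param pred,target numeric arrays of identical shape.
#' @export
loss_mae <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("shape mismatch")
  mean(abs(pred - target))
}

# subgradient of loss_mae w.r.t. pred
loss_mae_grad <- function(pred, target) sign(pred - target) / length(pred)

#' WGAN-GP adversarial loss
#'
#' `D(fake) - D(real) + eta * (||grad_xhat D(xhat)||_2 - 1)^2`, where
#' `xhat = eps * real + (1 - eps) * fake` with `eps ~ U(0, 1)` drawn from
#' `seed`, and the critic value is the mean of its PatchGAN map.
#'
#' @param d a `critic_net`.
#' @param fake,real slices as 1 x N matrices (or arrays) of identical shape.
#' @param dims spatial dims of the slice.
#' @param eta gradient-penalty weight.
#' @param seed seed for the interpolation draw.
#' @return Scalar loss; components in attribute `"parts"`.
#' @export
loss_adversarial <- function(d, fake, real, dims, eta = 0.1, seed = 1L) {
  fake <- matrix(as.numeric(fake), 1)
  real <- matrix(as.numeric(real), 1)
  if (length(fake) != length(real)) stop("shape mismatch")
  set.seed(seed)
  eps <- stats::runif(1)
  xhat <- eps * real + (1 - eps) * fake
  df <- critic_forward(d, fake, dims)$value
  dr <- critic_forward(d, real, dims)$value
  fh <- critic_forward(d, xhat, dims, keep = TRUE)
  gx <- critic_backward(d, fh$cache)$dx
  gnorm <- sqrt(sum(gx^2))
  loss <- df - dr + eta * (gnorm - 1)^2
  attr(loss, "parts") <- c(d_fake = df, d_real = dr, grad_norm = gnorm)
  loss
}

#' Perceptual (feature-space) loss
#'
#' `||phi(pred) - phi(target)||_2^2 / (W * H * C)` on the extractor's final
#' feature map.
#' @param fx a [build_feature_extractor()] object; passing `NULL` is a
#'   configuration error, never a silent fallback.
#' @param pred,target slices (1 x N matrices or 2D arrays).
#' @param dims spatial dims.
#' @export
loss_perceptual <- function(fx, pred, target, dims) {
  if (is.null(fx) || !inherits(fx, "feature_extractor"))
    stop("perceptual loss requires a configured feature extractor")
  pred <- matrix(as.numeric(pred), 1)
  target <- matrix(as.numeric(target), 1)
  if (length(pred) != length(target)) stop("shape mismatch")
  fp <- fx_forward(fx, pred, dims)
  ft <- fx_forward(fx, target, dims)
  sum((fp$features - ft$features)^2) / length(fp$features)
}

# value + gradient w.r.t. pred (training path)
loss_perceptual_grad <- function(fx, pred, target, dims) {
  fp <- fx_forward(fx, pred, dims, keep = TRUE)
  ft <- fx_forward(fx, target, dims)
  diff <- fp$features - ft$features
  n <- length(diff)
  list(value = sum(diff^2) / n,
       grad = fx_backward_input(fx, fp$cache, 2 * diff / n, fp$dims))
}

#' Combined Phase-2 objective
#'
#' @param kind `"mae"`, `"al-mae"` or `"pl-mae"`.
#' @param mae MAE component.
#' @param al,pl adversarial / perceptual components (required by their kinds).
#' @param config a [loss_config()].
#' @export
loss_combined <- function(kind = c("mae", "al-mae", "pl-mae"), mae,
                          al = NULL, pl = NULL, config = loss_config()) {
  kind <- match.arg(kind)
  switch(kind,
         "mae" = mae,
         "al-mae" = {
           if (is.null(al)) stop("al-mae requires the adversarial component")
           mae + config$lambda1 * al
         },
         "pl-mae" = {
           if (is.null(pl)) stop("pl-mae requires the perceptual component")
           mae + config$lambda2 * pl
         })
}
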