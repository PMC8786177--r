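# Two-phase training pipeline: dataset splitting, patch extraction, Phase-1
# (3D, MAE) training, aggregation into coronal slices, Phase-2 (2D) training,
# and full-volume inference.

# attenuation display window used to map volumes into the network domain
atten_window <- c(0.0456, 0.0844)

norm_window <- function(x, w = atten_window) (x - w[1]) / (w[2] - w[1])
denorm_window <- function(x, w = atten_window) x * (w[2] - w[1]) + w[1]

#' Training configuration
#'
#' Adam hyperparameters shared by both phases.
#' @param alpha learning rate (default 5e-3).
#' @param beta1,beta2 Adam moment decays (defaults 0.9 / 0.999).
#' @param batch_size images per step (default 2).
#' @param epochs training epochs (default 100).
#' @param n_critic critic updates per generator step for the adversarial
#'   objective (default 5).
#' @param seed seed controlling initialization and batch order.
#' @export
train_config <- function(alpha = 5e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 2L, epochs = 100L, n_critic = 5L,
                         seed = 1L) {
  stopifnot(alpha > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_critic = as.integer(n_critic),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split volume pairs into the two-phase train/validation/test sets
#'
#' Phase 1 uses a 1:1:3 split; the Phase-1 test set is further split 1:1:1
#' for Phase-2 training, validation and testing. Membership is a seeded
#' shuffle of the pair indices.
#'
#' @param n_pairs number of volume pairs (divisible by 5; 100 at full scale).
#' @param seed shuffle seed.
#' @return Nested index lists `$phase1$train/val/test`, `$phase2$train/val/test`.
#' @export
split_dataset <- function(n_pairs, seed = 1L) {
  if (n_pairs < 5 || n_pairs %% 5 != 0)
    stop("n_pairs must be a positive multiple of 5")
  set.seed(seed)
  idx <- sample.int(n_pairs)
  n5 <- n_pairs / 5
  p1 <- list(train = sort(idx[seq_len(n5)]),
             val = sort(idx[n5 + seq_len(n5)]),
             test = sort(idx[2 * n5 + seq_len(3 * n5)]))
  t3 <- length(p1$test) / 3
  p2 <- list(train = p1$test[seq_len(t3)],
             val = p1$test[t3 + seq_len(t3)],
             test = p1$test[2 * t3 + seq_len(t3)])
  structure(list(phase1 = p1, phase2 = p2, n_pairs = n_pairs, seed = seed),
            class = "dataset_split")
}

# regular non-overlapping tiling offsets (1-based corner indices)
tile_offsets <- function(dims, side) {
  if (any(dims %% side != 0))
    stop("volume sides must be divisible by the patch side")
  as.matrix(expand.grid(x = seq(1, dims[1], by = side),
                        y = seq(1, dims[2], by = side),
                        z = seq(1, dims[3], by = side)))
}

tile_volume <- function(arr, side) {
  off <- tile_offsets(dim(arr), side)
  patches <- lapply(seq_len(nrow(off)), function(i) {
    o <- off[i, ]
    arr[o[1]:(o[1] + side - 1), o[2]:(o[2] + side - 1), o[3]:(o[3] + side - 1)]
  })
  list(patches = patches, offsets = off, dims = dim(arr), side = side)
}

untile_volume <- function(patches, offsets, dims, side) {
  out <- array(0, dim = dims)
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    out[o[1]:(o[1] + side - 1), o[2]:(o[2] + side - 1), o[3]:(o[3] + side - 1)] <-
      patches[[i]]
  }
  out
}

#' Extract paired non-overlapping patches from a DBT/CBCT volume pair
#'
#' @param volume_pair list with 3D arrays `$dbt` and `$cbct` of equal shape.
#' @param patch_side cubic patch side (48 at full scale; 288x288x144 tiles
#'   into 6 x 6 x 3 = 108 patches).
#' @return A `patch_set` with paired patch lists and offset bookkeeping.
#' @export
extract_patches <- function(volume_pair, patch_side = 48L) {
  stopifnot(is.list(volume_pair), !is.null(volume_pair$dbt),
            !is.null(volume_pair$cbct),
            identical(dim(volume_pair$dbt), dim(volume_pair$cbct)))
  td <- tile_volume(unclass(volume_pair$dbt), patch_side)
  tc <- tile_volume(unclass(volume_pair$cbct), patch_side)
  structure(list(dbt = td$patches, cbct = tc$patches, offsets = td$offsets,
                 dims = td$dims, patch_side = as.integer(patch_side)),
            class = "patch_set")
}

# merge patch sets from several volumes
concat_patch_sets <- function(sets) {
  structure(list(dbt = do.call(c, lapply(sets, `[[`, "dbt")),
                 cbct = do.call(c, lapply(sets, `[[`, "cbct")),
                 offsets = NULL, dims = sets[[1]]$dims,
                 patch_side = sets[[1]]$patch_side),
            class = "patch_set")
}

#' @export
length.patch_set <- function(x) length(x$dbt)

new_trained_model <- function(net, phase, history, cfg, ...) {
  structure(c(list(net = net, phase = phase, history = history, cfg = cfg),
              list(...)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  n_ep <- length(x$history$train)
  cat(sprintf("<trained_model> phase %d, %d epochs, final train loss %.4g\n",
              x$phase, n_ep, utils::tail(x$history$train, 1)))
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints embed the architecture spec and parameters; reloading gives a
#' bit-identical forward pass.
#' @param model a `trained_model`.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) saveRDS(model, path)

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Train the Phase-1 3D residual network
#'
#' Adam on the MAE objective over paired 48^3 (or reduced-scale) patches,
#' batch-averaged; volumes are mapped into the display window before entering
#' the network. Logs per-epoch training (and optional validation) loss.
#'
#' @param patches a `patch_set` (training pairs).
#' @param cfg a [train_config()].
#' @param spec a [phase1_spec()].
#' @param val_patches optional `patch_set` for validation loss tracking.
#' @param verbose print per-epoch losses.
#' @return A `trained_model` holding the network with final and best
#'   (lowest validation, else lowest training loss) parameters.
#' @export
train_phase1 <- function(patches, cfg = train_config(), spec = phase1_spec(),
                         val_patches = NULL, verbose = FALSE) {
  stopifnot(inherits(patches, "patch_set"), length(patches) > 0)
  side <- patches$patch_side
  dims <- rep(side, 3L)
  xs <- lapply(patches$dbt, function(p) matrix(norm_window(as.numeric(p)), 1))
  ys <- lapply(patches$cbct, function(p) matrix(norm_window(as.numeric(p)), 1))
  vxs <- if (!is.null(val_patches))
    lapply(val_patches$dbt, function(p) matrix(norm_window(as.numeric(p)), 1))
  vys <- if (!is.null(val_patches))
    lapply(val_patches$cbct, function(p) matrix(norm_window(as.numeric(p)), 1))

  net <- build_phase1(spec)
  st <- adam_init(net$par)
  hist <- list(train = numeric(0), val = numeric(0))
  best <- list(loss = Inf, par = net$par)

  n <- length(xs)
  for (ep in seq_len(cfg$epochs)) {
    set.seed(cfg$seed * 131L + ep)
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bidx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      grads <- list()
      bl <- 0
      for (i in bidx) {
        fw <- phase1_forward(net, xs[[i]], dims, keep = TRUE)
        l <- loss_mae(fw$y, ys[[i]])
        dy <- loss_mae_grad(fw$y, ys[[i]]) / length(bidx)
        bw <- phase1_backward(net, fw$cache, dy, dims)
        grads <- add_grads(grads, bw$grads)
        bl <- bl + l / length(bidx)
      }
      if (!is.finite(bl)) stop(sprintf("training diverged at epoch %d (loss %g)", ep, bl))
      up <- adam_step(net$par, grads, st, cfg$alpha, cfg$beta1, cfg$beta2)
      net$par <- up$par; st <- up$state
      ep_losses <- c(ep_losses, bl)
    }
    hist$train <- c(hist$train, mean(ep_losses))
    sel_loss <- mean(ep_losses)
    if (!is.null(vxs)) {
      vl <- mean(vapply(seq_along(vxs), function(i)
        loss_mae(phase1_forward(net, vxs[[i]], dims)$y, vys[[i]]), 0))
      hist$val <- c(hist$val, vl)
      sel_loss <- vl
    }
    if (sel_loss < best$loss) best <- list(loss = sel_loss, par = net$par)
    if (verbose)
      message(sprintf("phase1 epoch %d: train %.5f%s", ep, mean(ep_losses),
                      if (!is.null(vxs)) sprintf(" val %.5f", utils::tail(hist$val, 1)) else ""))
  }
  new_trained_model(net, 1L, hist, cfg, patch_side = side, best_par = best$par)
}

# apply Phase 1 to a full volume (normalized domain in and out)
apply_phase1_norm <- function(model, vol_norm, patch_side = model$patch_side) {
  t <- tile_volume(vol_norm, patch_side)
  dims <- rep(patch_side, 3L)
  out <- lapply(t$patches, function(p) {
    y <- phase1_forward(model$net, matrix(as.numeric(p), 1), dims)$y
    array(y, dim = dims)
  })
  untile_volume(out, t$offsets, t$dims, patch_side)
}

# coronal slices: planes x-z, one per y index
coronal_slices <- function(arr) lapply(seq_len(dim(arr)[2]), function(j) arr[, j, ])

stack_coronal <- function(slices, dims) {
  out <- array(0, dim = dims)
  for (j in seq_along(slices)) out[, j, ] <- slices[[j]]
  out
}

#' Aggregate Phase-1 outputs and slice along the coronal plane
#'
#' Runs the trained Phase-1 network patchwise over each DBT volume,
#' reassembles the full volume, and cuts it into coronal (x-z) slices. Targets
#' are the matching CBCT coronal slices; setting
#' `targets = "phase1_of_cbct"` instead passes the CBCT volumes through
#' Phase 1 as well (the algorithm-literal variant).
#'
#' @param model trained Phase-1 `trained_model`.
#' @param pairs list of volume pairs (each `list(dbt =, cbct =)`).
#' @param targets `"cbct"` (default) or `"phase1_of_cbct"`.
#' @return A `slice_set` in the normalized display-window domain.
#' @export
aggregate_and_slice <- function(model, pairs,
                                targets = c("cbct", "phase1_of_cbct")) {
  targets <- match.arg(targets)
  stopifnot(inherits(model, "trained_model"), model$phase == 1L)
  zs <- list(); xs <- list(); vol_id <- integer(0)
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    zhat <- apply_phase1_norm(model, norm_window(unclass(pr$dbt)))
    xv <- norm_window(unclass(pr$cbct))
    if (targets == "phase1_of_cbct") xv <- apply_phase1_norm(model, xv)
    zs <- c(zs, coronal_slices(zhat))
    xs <- c(xs, coronal_slices(xv))
    vol_id <- c(vol_id, rep(k, dim(zhat)[2]))
  }
  structure(list(z = zs, x = xs, volume = vol_id,
                 slice_dims = dim(zs[[1]]), targets = targets),
            class = "slice_set")
}

#' @export
length.slice_set <- function(x) length(x$z)

#' Train the Phase-2 coronal U-Net
#'
#' Adam with the same hyperparameters as Phase 1 on coronal slice pairs, under
#' one of three objectives: plain MAE, MAE + lambda1 * adversarial (WGAN-GP,
#' critic trained jointly with `n_critic` updates per generator step), or
#' MAE + lambda2 * perceptual.
#'
#' @param slices a `slice_set` from [aggregate_and_slice()].
#' @param cfg a [train_config()].
#' @param loss_kind `"mae"`, `"al-mae"` or `"pl-mae"`.
#' @param spec a [phase2_spec()].
#' @param loss_cfg a [loss_config()]; must carry a feature extractor for
#'   `"pl-mae"`.
#' @param critic_spec a [discriminator_spec()] for `"al-mae"`.
#' @param val_slices optional `slice_set` for validation loss tracking.
#' @param verbose print per-epoch losses.
#' @export
train_phase2 <- function(slices, cfg = train_config(),
                         loss_kind = c("mae", "al-mae", "pl-mae"),
                         spec = phase2_spec(), loss_cfg = loss_config(),
                         critic_spec = discriminator_spec(),
                         val_slices = NULL, verbose = FALSE) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(inherits(slices, "slice_set"), length(slices) > 0)
  if (loss_kind == "pl-mae" && is.null(loss_cfg$feature_extractor))
    stop("pl-mae requires loss_config(feature_extractor = ...)")
  dims <- slices$slice_dims
  unet_check_dims(spec, dims)
  zs <- lapply(slices$z, function(s) matrix(as.numeric(s), 1))
  xs <- lapply(slices$x, function(s) matrix(as.numeric(s), 1))

  net <- build_phase2(spec)
  st <- adam_init(net$par)
  critic <- NULL; cst <- NULL
  if (loss_kind == "al-mae") {
    critic <- build_discriminator(critic_spec)
    cst <- adam_init(critic$par)
  }
  hist <- list(train = numeric(0), val = numeric(0))
  best <- list(loss = Inf, par = net$par)
  n <- length(zs)

  for (ep in seq_len(cfg$epochs)) {
    set.seed(cfg$seed * 257L + ep)
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bidx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      preds <- list(); caches <- list()
      for (j in seq_along(bidx)) {
        fw <- phase2_forward(net, zs[[bidx[j]]], dims, keep = TRUE)
        preds[[j]] <- fw$y; caches[[j]] <- fw$cache
      }
      if (loss_kind == "al-mae") {
        for (cit in seq_len(cfg$n_critic)) {
          cg <- list()
          for (j in seq_along(bidx)) {
            cg <- add_grads(cg, critic_gp_grads(critic, preds[[j]],
                                                xs[[bidx[j]]], dims,
                                                loss_cfg$eta,
                                                seed = cfg$seed + ep * 1000L + cit))
          }
          cg <- scale_grads(cg, 1 / length(bidx))
          upc <- adam_step(critic$par, cg, cst, cfg$alpha, cfg$beta1, cfg$beta2)
          critic$par <- upc$par; cst <- upc$state
        }
      }
      grads <- list()
      bl <- 0
      for (j in seq_along(bidx)) {
        i <- bidx[j]
        lm <- loss_mae(preds[[j]], xs[[i]])
        dy <- loss_mae_grad(preds[[j]], xs[[i]])
        ltot <- lm
        if (loss_kind == "pl-mae") {
          pg <- loss_perceptual_grad(loss_cfg$feature_extractor, preds[[j]],
                                     xs[[i]], dims)
          ltot <- ltot + loss_cfg$lambda2 * pg$value
          dy <- dy + loss_cfg$lambda2 * pg$grad
        } else if (loss_kind == "al-mae") {
          fh <- critic_forward(critic, preds[[j]], dims, keep = TRUE)
          dfake <- critic_backward(critic, fh$cache)$dx
          ltot <- ltot + loss_cfg$lambda1 * fh$value
          dy <- dy + loss_cfg$lambda1 * dfake
        }
        bw <- phase2_backward(net, caches[[j]], dy / length(bidx), dims)
        grads <- add_grads(grads, bw$grads)
        bl <- bl + ltot / length(bidx)
      }
      if (!is.finite(bl)) stop(sprintf("training diverged at epoch %d (loss %g)", ep, bl))
      up <- adam_step(net$par, grads, st, cfg$alpha, cfg$beta1, cfg$beta2)
      net$par <- up$par; st <- up$state
      ep_losses <- c(ep_losses, bl)
    }
    hist$train <- c(hist$train, mean(ep_losses))
    sel_loss <- mean(ep_losses)
    if (!is.null(val_slices)) {
      vl <- mean(vapply(seq_along(val_slices$z), function(i)
        loss_mae(phase2_forward(net, matrix(as.numeric(val_slices$z[[i]]), 1),
                                dims)$y,
                 matrix(as.numeric(val_slices$x[[i]]), 1)), 0))
      hist$val <- c(hist$val, vl)
      sel_loss <- vl
    }
    if (sel_loss < best$loss) best <- list(loss = sel_loss, par = net$par)
    if (verbose)
      message(sprintf("phase2[%s] epoch %d: train %.5f", loss_kind, ep,
                      mean(ep_losses)))
  }
  new_trained_model(net, 2L, hist, cfg, loss_kind = loss_kind,
                    best_par = best$par, critic = critic)
}

# critic gradient for one fake/real pair: d/dtheta of
#   D(fake) - D(real) + eta * (||grad_xhat D(xhat)|| - 1)^2
# The penalty's parameter gradient is a mixed second derivative; it is
# computed as a central finite difference of grad_theta D along the unit
# gradient direction, which is exact almost everywhere for a piecewise-linear
# (ReLU) critic.
critic_gp_grads <- function(critic, fake, real, dims, eta, seed,
                            fd_eps = 1e-3) {
  ff <- critic_forward(critic, fake, dims, keep = TRUE)
  fr <- critic_forward(critic, real, dims, keep = TRUE)
  g <- add_grads(critic_backward(critic, ff$cache)$grads,
                 scale_grads(critic_backward(critic, fr$cache)$grads, -1))
  set.seed(seed)
  eps <- stats::runif(1)
  xhat <- eps * real + (1 - eps) * fake
  fh <- critic_forward(critic, xhat, dims, keep = TRUE)
  gx <- critic_backward(critic, fh$cache)$dx
  gnorm <- sqrt(sum(gx^2))
  if (gnorm > 0) {
    u <- gx / gnorm
    fp <- critic_forward(critic, xhat + fd_eps * u, dims, keep = TRUE)
    fm <- critic_forward(critic, xhat - fd_eps * u, dims, keep = TRUE)
    hvp <- scale_grads(add_grads(critic_backward(critic, fp$cache)$grads,
                                 scale_grads(critic_backward(critic, fm$cache)$grads, -1)),
                       1 / (2 * fd_eps))
    g <- add_grads(g, scale_grads(hvp, 2 * eta * (gnorm - 1)))
  }
  g
}

#' Deblur a DBT volume with the trained two-phase model
#'
#' Phase 1 runs patchwise over non-overlapping tiles, the reassembled volume
#' is cut into coronal slices, Phase 2 refines each slice, and the result is
#' reassembled and mapped back to the attenuation scale.
#'
#' @param volume DBT [attenuation_volume()] (or plain array).
#' @param g1,g2 trained Phase-1 / Phase-2 models.
#' @return Deblurred volume of the same shape.
#' @export
infer <- function(volume, g1, g2) {
  stopifnot(inherits(g1, "trained_model"), g1$phase == 1L,
            inherits(g2, "trained_model"), g2$phase == 2L)
  arr <- unclass(volume)
  zhat <- apply_phase1_norm(g1, norm_window(arr))
  dims2 <- c(dim(arr)[1], dim(arr)[3])
  out_slices <- lapply(coronal_slices(zhat), function(s)
    array(phase2_forward(g2$net, matrix(as.numeric(s), 1), dims2)$y, dim = dims2))
  out <- denorm_window(stack_coronal(out_slices, dim(arr)))
  if (inherits(volume, "attenuation_volume"))
    attenuation_volume(out, voxel_size_of(volume), origin_of(volume))
  else out
}
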