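#' Phase-1 network specification
#'
#' A 3D residual network: one input convolution (1 -> n_filters), `n_blocks`
#' residual blocks (conv - ReLU - conv plus identity), and one output
#' convolution (n_filters -> 1). All convolutions are 3x3x3, stride 1,
#' zero same-padding, no normalization layers.
#'
#' @param n_blocks residual blocks (default 10).
#' @param n_filters filters per convolution (default 40).
#' @param seed initialization seed.
#' @export
phase1_spec <- function(n_blocks = 10L, n_filters = 40L, seed = 1L) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(n_blocks = as.integer(n_blocks),
                 n_filters = as.integer(n_filters),
                 kernel = 3L, nd = 3L, seed = as.integer(seed)),
            class = "phase1_spec")
}

#' Phase-2 network specification
#'
#' A 2D U-Net: `pooling_levels` encoder levels of two 3x3 conv+ReLU layers
#' followed by 2x2 max pooling, a two-conv bottleneck, and a mirrored decoder
#' (2x nearest-neighbor upsampling + conv, skip concatenation, two convs),
#' closed by a 1x1 single-channel convolution. Filters double per pooling and
#' halve per upsampling.
#'
#' @param base_filters filters at the first level (default 32).
#' @param pooling_levels encoder depth (default 4); input sides must be
#'   divisible by `2^pooling_levels`.
#' @param seed initialization seed.
#' @export
phase2_spec <- function(base_filters = 32L, pooling_levels = 4L, seed = 1L) {
  structure(list(base_filters = as.integer(base_filters),
                 pooling_levels = as.integer(pooling_levels),
                 convs_per_level = 2L, kernel = 3L, seed = as.integer(seed)),
            class = "phase2_spec")
}

#' PatchGAN critic specification
#'
#' A strided 4x4 convolution stack (LeakyReLU 0.2, no normalization, as WGAN-GP
#' requires) whose output map has an effective receptive field of 142 ~ 144
#' pixels: four stride-2 4x4 convolutions, two stride-1 4x4 convolutions, and
#' a 1x1 projection to a scalar patch map, averaged into the critic value.
#'
#' @param base_filters filters of the first convolution (doubling up the
#'   stack, default 64).
#' @param seed initialization seed.
#' @export
discriminator_spec <- function(base_filters = 64L, seed = 1L) {
  structure(list(base_filters = as.integer(base_filters), seed = as.integer(seed)),
            class = "discriminator_spec")
}

# ---- Phase 1: 3D residual network ------------------------------------------

#' Build the Phase-1 3D residual network
#' @param spec a [phase1_spec()].
#' @return A `phase1_net` with seeded parameters.
#' @export
build_phase1 <- function(spec) {
  stopifnot(inherits(spec, "phase1_spec"))
  f <- spec$n_filters
  k3 <- spec$kernel^spec$nd
  set.seed(spec$seed)
  par <- list()
  par$in.w <- he_weights(f, 1, k3); par$in.b <- numeric(f)
  for (b in seq_len(spec$n_blocks)) {
    par[[sprintf("blk%d.w1", b)]] <- he_weights(f, f, k3)
    par[[sprintf("blk%d.b1", b)]] <- numeric(f)
    par[[sprintf("blk%d.w2", b)]] <- he_weights(f, f, k3)
    par[[sprintf("blk%d.b2", b)]] <- numeric(f)
  }
  par$out.w <- he_weights(1, f, k3, gain = 1); par$out.b <- 0
  structure(list(spec = spec, par = par,
                 offsets = conv_offsets(spec$kernel, spec$nd)),
            class = c("phase1_net", "conv_net"))
}

phase1_forward <- function(net, x, dims, keep = FALSE) {
  # x: 1 x N matrix
  if (any(dims < net$spec$kernel)) stop("input smaller than the kernel")
  p <- net$par; off <- net$offsets
  cache <- if (keep) list(x = x) else NULL
  h <- conv_fwd(x, p$in.w, p$in.b, off, dims)
  if (keep) cache$h0 <- h
  for (b in seq_len(net$spec$n_blocks)) {
    a1 <- conv_fwd(h, p[[sprintf("blk%d.w1", b)]], p[[sprintf("blk%d.b1", b)]], off, dims)
    r <- relu_fwd(a1)
    a2 <- conv_fwd(r$y, p[[sprintf("blk%d.w2", b)]], p[[sprintf("blk%d.b2", b)]], off, dims)
    if (keep) cache[[sprintf("blk%d", b)]] <- list(hin = h, mask = r$mask, r = r$y)
    h <- h + a2
  }
  y <- conv_fwd(h, p$out.w, p$out.b, off, dims)
  if (keep) cache$h_last <- h
  list(y = y, cache = cache)
}

phase1_backward <- function(net, cache, dy, dims) {
  p <- net$par; off <- net$offsets
  g <- list()
  bo <- conv_bwd(dy, cache$h_last, p$out.w, off, dims)
  g$out.w <- bo$dw; g$out.b <- bo$db
  dh <- bo$dx
  for (b in rev(seq_len(net$spec$n_blocks))) {
    cb <- cache[[sprintf("blk%d", b)]]
    b2 <- conv_bwd(dh, cb$r, p[[sprintf("blk%d.w2", b)]], off, dims)
    g[[sprintf("blk%d.w2", b)]] <- b2$dw
    g[[sprintf("blk%d.b2", b)]] <- b2$db
    dr <- relu_bwd(b2$dx, cb$mask)
    b1 <- conv_bwd(dr, cb$hin, p[[sprintf("blk%d.w1", b)]], off, dims)
    g[[sprintf("blk%d.w1", b)]] <- b1$dw
    g[[sprintf("blk%d.b1", b)]] <- b1$db
    dh <- dh + b1$dx   # identity path + block path
  }
  bi <- conv_bwd(dh, cache$x, p$in.w, off, dims)
  g$in.w <- bi$dw; g$in.b <- bi$db
  list(dx = bi$dx, grads = g)
}

# ---- Phase 2: 2D U-Net ------------------------------------------------------

unet_filters <- function(spec, level) spec$base_filters * 2L^(level - 1L)

#' Build the Phase-2 U-Net
#' @param spec a [phase2_spec()].
#' @return A `phase2_net` with seeded parameters.
#' @export
build_phase2 <- function(spec) {
  stopifnot(inherits(spec, "phase2_spec"))
  L <- spec$pooling_levels
  k2 <- spec$kernel^2
  set.seed(spec$seed)
  par <- list()
  cin <- 1L
  for (l in seq_len(L)) {
    f <- unet_filters(spec, l)
    par[[sprintf("enc%d.w1", l)]] <- he_weights(f, cin, k2)
    par[[sprintf("enc%d.b1", l)]] <- numeric(f)
    par[[sprintf("enc%d.w2", l)]] <- he_weights(f, f, k2)
    par[[sprintf("enc%d.b2", l)]] <- numeric(f)
    cin <- f
  }
  fb <- unet_filters(spec, L + 1L)
  par$bot.w1 <- he_weights(fb, cin, k2); par$bot.b1 <- numeric(fb)
  par$bot.w2 <- he_weights(fb, fb, k2); par$bot.b2 <- numeric(fb)
  for (l in rev(seq_len(L))) {
    f <- unet_filters(spec, l)
    fbelow <- unet_filters(spec, l + 1L)
    par[[sprintf("dec%d.wu", l)]] <- he_weights(f, fbelow, k2)  # up conv halves filters
    par[[sprintf("dec%d.bu", l)]] <- numeric(f)
    par[[sprintf("dec%d.w1", l)]] <- he_weights(f, 2L * f, k2)  # after skip concat
    par[[sprintf("dec%d.b1", l)]] <- numeric(f)
    par[[sprintf("dec%d.w2", l)]] <- he_weights(f, f, k2)
    par[[sprintf("dec%d.b2", l)]] <- numeric(f)
  }
  par$out.w <- he_weights(1, spec$base_filters, 1L, gain = 1)
  par$out.b <- 0
  structure(list(spec = spec, par = par,
                 offsets = conv_offsets(spec$kernel, 2L),
                 offsets1 = conv_offsets(1L, 2L)),
            class = c("phase2_net", "conv_net"))
}

unet_check_dims <- function(spec, dims) {
  div <- 2L^spec$pooling_levels
  if (any(dims %% div != 0))
    stop(sprintf("input sides must be divisible by %d", div))
}

phase2_forward <- function(net, x, dims, keep = FALSE) {
  spec <- net$spec; p <- net$par; off <- net$offsets
  unet_check_dims(spec, dims)
  L <- spec$pooling_levels
  cache <- if (keep) list() else NULL
  h <- x; d <- dims
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- conv_fwd(h, p[[sprintf("enc%d.w1", l)]], p[[sprintf("enc%d.b1", l)]], off, d)
    r1 <- relu_fwd(a1)
    a2 <- conv_fwd(r1$y, p[[sprintf("enc%d.w2", l)]], p[[sprintf("enc%d.b2", l)]], off, d)
    r2 <- relu_fwd(a2)
    pl <- maxpool2_fwd(r2$y, d)
    if (keep) cache[[sprintf("enc%d", l)]] <-
      list(hin = h, m1 = r1$mask, r1 = r1$y, m2 = r2$mask, r2 = r2$y,
           pool = pl, dims = d)
    skips[[l]] <- r2$y
    h <- pl$y; d <- pl$dims_out
  }
  a1 <- conv_fwd(h, p$bot.w1, p$bot.b1, off, d)
  r1 <- relu_fwd(a1)
  a2 <- conv_fwd(r1$y, p$bot.w2, p$bot.b2, off, d)
  r2 <- relu_fwd(a2)
  if (keep) cache$bot <- list(hin = h, m1 = r1$mask, r1 = r1$y, m2 = r2$mask,
                              dims = d)
  h <- r2$y
  for (l in rev(seq_len(L))) {
    up <- upsample2_fwd(h, d)
    d <- up$dims_out
    au <- conv_fwd(up$y, p[[sprintf("dec%d.wu", l)]], p[[sprintf("dec%d.bu", l)]], off, d)
    ru <- relu_fwd(au)
    hc <- rbind(ru$y, skips[[l]])
    a1 <- conv_fwd(hc, p[[sprintf("dec%d.w1", l)]], p[[sprintf("dec%d.b1", l)]], off, d)
    r1 <- relu_fwd(a1)
    a2 <- conv_fwd(r1$y, p[[sprintf("dec%d.w2", l)]], p[[sprintf("dec%d.b2", l)]], off, d)
    r2 <- relu_fwd(a2)
    if (keep) cache[[sprintf("dec%d", l)]] <-
      list(up = up, upin = up$y, mu = ru$mask, hc = hc, m1 = r1$mask,
           r1 = r1$y, m2 = r2$mask, dims = d)
    h <- r2$y
  }
  y <- conv_fwd(h, p$out.w, p$out.b, net$offsets1, d)
  if (keep) cache$h_last <- h
  list(y = y, cache = cache)
}

phase2_backward <- function(net, cache, dy, dims) {
  spec <- net$spec; p <- net$par; off <- net$offsets
  L <- spec$pooling_levels
  g <- list()
  d <- dims
  bo <- conv_bwd(dy, cache$h_last, p$out.w, net$offsets1, d)
  g$out.w <- bo$dw; g$out.b <- bo$db
  dh <- bo$dx
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    cb <- cache[[sprintf("dec%d", l)]]
    d <- cb$dims
    d2 <- relu_bwd(dh, cb$m2)
    b2 <- conv_bwd(d2, cb$r1, p[[sprintf("dec%d.w2", l)]], off, d)
    g[[sprintf("dec%d.w2", l)]] <- b2$dw; g[[sprintf("dec%d.b2", l)]] <- b2$db
    d1 <- relu_bwd(b2$dx, cb$m1)
    b1 <- conv_bwd(d1, cb$hc, p[[sprintf("dec%d.w1", l)]], off, d)
    g[[sprintf("dec%d.w1", l)]] <- b1$dw; g[[sprintf("dec%d.b1", l)]] <- b1$db
    f <- unet_filters(spec, l)
    dru <- b1$dx[seq_len(f), , drop = FALSE]
    dskips[[l]] <- b1$dx[f + seq_len(f), , drop = FALSE]
    du <- relu_bwd(dru, cb$mu)
    bu <- conv_bwd(du, cb$upin, p[[sprintf("dec%d.wu", l)]], off, d)
    g[[sprintf("dec%d.wu", l)]] <- bu$dw; g[[sprintf("dec%d.bu", l)]] <- bu$db
    dh <- upsample2_bwd(bu$dx, cb$up, d / 2L)
  }
  cb <- cache$bot
  d <- cb$dims
  d2 <- relu_bwd(dh, cb$m2)
  b2 <- conv_bwd(d2, cb$r1, p$bot.w2, off, d)
  g$bot.w2 <- b2$dw; g$bot.b2 <- b2$db
  d1 <- relu_bwd(b2$dx, cb$m1)
  b1 <- conv_bwd(d1, cb$hin, p$bot.w1, off, d)
  g$bot.w1 <- b1$dw; g$bot.b1 <- b1$db
  dh <- b1$dx
  for (l in rev(seq_len(L))) {
    cb <- cache[[sprintf("enc%d", l)]]
    d <- cb$dims
    dpool <- maxpool2_bwd(dh, cb$pool, d)
    dr2 <- dpool + dskips[[l]]
    d2 <- relu_bwd(dr2, cb$m2)
    b2 <- conv_bwd(d2, cb$r1, p[[sprintf("enc%d.w2", l)]], off, d)
    g[[sprintf("enc%d.w2", l)]] <- b2$dw; g[[sprintf("enc%d.b2", l)]] <- b2$db
    d1 <- relu_bwd(b2$dx, cb$m1)
    b1 <- conv_bwd(d1, cb$hin, p[[sprintf("enc%d.w1", l)]], off, d)
    g[[sprintf("enc%d.w1", l)]] <- b1$dw; g[[sprintf("enc%d.b1", l)]] <- b1$db
    dh <- b1$dx
  }
  list(dx = dh, grads = g)
}

# ---- PatchGAN critic --------------------------------------------------------

critic_layer_table <- function(base) {
  data.frame(name = c("c1", "c2", "c3", "c4", "c5", "c6", "out"),
             k = c(4L, 4L, 4L, 4L, 4L, 4L, 1L),
             stride = c(2L, 2L, 2L, 2L, 1L, 1L, 1L),
             cout = c(base, 2L * base, 4L * base, 8L * base, 8L * base,
                      8L * base, 1L))
}

#' Build the PatchGAN critic
#' @param spec a [discriminator_spec()].
#' @return A `critic_net`; its scalar value is the mean of the patch map.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  tab <- critic_layer_table(spec$base_filters)
  set.seed(spec$seed)
  par <- list()
  cin <- 1L
  for (i in seq_len(nrow(tab))) {
    par[[paste0(tab$name[i], ".w")]] <- he_weights(tab$cout[i], cin, tab$k[i]^2)
    par[[paste0(tab$name[i], ".b")]] <- numeric(tab$cout[i])
    cin <- tab$cout[i]
  }
  structure(list(spec = spec, par = par, tab = tab),
            class = c("critic_net", "conv_net"))
}

critic_forward <- function(net, x, dims, keep = FALSE) {
  p <- net$par; tab <- net$tab
  h <- x; d <- dims
  cache <- if (keep) list(dims_in = dims) else NULL
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    off <- conv_offsets(tab$k[i], 2L)
    a <- sconv_fwd(h, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]], off, d, tab$stride[i])
    dn <- ceiling(d / tab$stride[i])
    if (nm != "out") {
      r <- lrelu_fwd(a)
      if (keep) cache[[nm]] <- list(hin = h, cache_act = r, dims = d)
      h <- r$y
    } else {
      if (keep) cache[[nm]] <- list(hin = h, dims = d)
      h <- a
    }
    d <- dn
  }
  if (keep) cache$dims_map <- d
  list(value = mean(h), map = h, cache = cache)
}

critic_backward <- function(net, cache, dvalue = 1) {
  p <- net$par; tab <- net$tab
  nmap <- prod(cache$dims_map)
  dh <- matrix(dvalue / nmap, 1, nmap)
  g <- list()
  for (i in rev(seq_len(nrow(tab)))) {
    nm <- tab$name[i]
    off <- conv_offsets(tab$k[i], 2L)
    cb <- cache[[nm]]
    if (nm != "out") dh <- lrelu_bwd(dh, cb$cache_act)
    bw <- sconv_bwd(dh, cb$hin, p[[paste0(nm, ".w")]], off, cb$dims, tab$stride[i])
    g[[paste0(nm, ".w")]] <- bw$dw; g[[paste0(nm, ".b")]] <- bw$db
    dh <- bw$dx
  }
  list(dx = dh, grads = g)
}

# ---- Perceptual feature extractor ------------------------------------------

#' Build the perceptual feature extractor
#'
#' A VGG-16-style stack of the 13 3x3 convolution layers (channel widths
#' base, base, 2x, 2x, 4x, 4x, 4x, 8x, 8x, 8x, 8x, 8x, 8x with 2x2 max pooling
#' after layers 2, 4, 7 and 10), evaluated through its last convolution.
#' Weights are seeded random draws unless a pretrained parameter list of the
#' same shapes is supplied; a random extractor still defines a valid
#' perceptual metric for testing, but does not carry natural-image priors.
#'
#' @param base_filters width of the first block (64 for the VGG-16 layout).
#' @param seed initialization seed.
#' @param pretrained optional named parameter list matching the layout.
#' @export
build_feature_extractor <- function(base_filters = 64L, seed = 1L,
                                    pretrained = NULL) {
  widths <- base_filters * c(1, 1, 2, 2, 4, 4, 4, 8, 8, 8, 8, 8, 8)
  pool_after <- c(2L, 4L, 7L, 10L)
  set.seed(seed)
  par <- list()
  cin <- 3L
  for (i in seq_along(widths)) {
    par[[sprintf("c%d.w", i)]] <- he_weights(widths[i], cin, 9L)
    par[[sprintf("c%d.b", i)]] <- numeric(widths[i])
    cin <- widths[i]
  }
  if (!is.null(pretrained)) {
    if (!identical(lapply(par, dim), lapply(pretrained[names(par)], dim)))
      stop("pretrained parameters do not match the extractor layout")
    par <- pretrained[names(par)]
  }
  structure(list(par = par, widths = widths, pool_after = pool_after,
                 offsets = conv_offsets(3L, 2L), seed = seed,
                 pretrained = !is.null(pretrained)),
            class = c("feature_extractor", "conv_net"))
}

# grayscale slice (1 x N, display-window units) -> 3-channel standardized input
fx_prepare <- function(x) rbind(x, x, x) |> (\(m) (m - 0.449) / 0.226)()

fx_forward <- function(fx, x, dims, keep = FALSE) {
  p <- fx$par; off <- fx$offsets
  h <- fx_prepare(x); d <- dims
  cache <- if (keep) list() else NULL
  for (i in seq_along(fx$widths)) {
    a <- conv_fwd(h, p[[sprintf("c%d.w", i)]], p[[sprintf("c%d.b", i)]], off, d)
    r <- relu_fwd(a)
    if (keep) cache[[sprintf("c%d", i)]] <- list(hin = h, mask = r$mask, dims = d)
    h <- r$y
    if (i %in% fx$pool_after) {
      pl <- maxpool2_fwd(h, d)
      if (keep) cache[[sprintf("p%d", i)]] <- list(pool = pl, dims = d)
      h <- pl$y; d <- pl$dims_out
    }
  }
  list(features = h, dims = d, cache = cache)
}

# backward to the single-channel input (no parameter gradients: the extractor
# is frozen)
fx_backward_input <- function(fx, cache, dfeat, dims_out) {
  p <- fx$par; off <- fx$offsets
  dh <- dfeat
  for (i in rev(seq_along(fx$widths))) {
    if (i %in% fx$pool_after) {
      cb <- cache[[sprintf("p%d", i)]]
      dh <- maxpool2_bwd(dh, cb$pool, cb$dims)
    }
    cb <- cache[[sprintf("c%d", i)]]
    dh <- relu_bwd(dh, cb$mask)
    dh <- cpp_conv_bwd_input(dh, p[[sprintf("c%d.w", i)]], off, as.integer(cb$dims))
  }
  # undo channel replication and standardization
  matrix(colSums(dh) / 0.226, 1)
}

# ---- receptive fields -------------------------------------------------------

#' Analytic receptive field of the Phase-1 network
#'
#' Layer-by-layer recursion: every 3x3x3 stride-1 convolution grows the field
#' by 2, over `2 * n_blocks + 2` convolutions.
#' @param spec a [phase1_spec()].
#' @return Side length in voxels.
#' @export
receptive_field_phase1 <- function(spec) {
  r <- 1L; j <- 1L
  for (i in seq_len(2L * spec$n_blocks + 2L)) r <- r + (spec$kernel - 1L) * j
  r
}

#' Analytic receptive field of the Phase-2 encoder bottleneck
#'
#' Recursion r <- r + (k - 1) * jump over the encoder convolutions and
#' poolings down to the bottleneck output.
#' @param spec a [phase2_spec()].
#' @param trace return the whole recursion sequence instead of the final value.
#' @return Side length in pixels (or the recursion sequence).
#' @export
receptive_field_phase2 <- function(spec, trace = FALSE) {
  r <- 1L; j <- 1L
  seqs <- integer(0)
  for (l in seq_len(spec$pooling_levels)) {
    for (cc in seq_len(spec$convs_per_level)) {
      r <- r + (spec$kernel - 1L) * j
      seqs <- c(seqs, r)
    }
    r <- r + 1L * j  # 2x2 pool, stride 2
    j <- j * 2L
    seqs <- c(seqs, r)
  }
  for (cc in seq_len(2L)) {
    r <- r + (spec$kernel - 1L) * j
    seqs <- c(seqs, r)
  }
  if (trace) seqs else r
}

#' Analytic receptive field of the critic map
#' @param spec a [discriminator_spec()].
#' @export
receptive_field_critic <- function(spec) {
  tab <- critic_layer_table(spec$base_filters)
  r <- 1L; j <- 1L
  for (i in seq_len(nrow(tab))) {
    r <- r + (tab$k[i] - 1L) * j
    j <- j * tab$stride[i]
  }
  r
}
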