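# Low-level network operations.
#
# Activations are (channels x positions) matrices; spatial dims are carried
# separately (length 2 for slices, 3 for patches) in R's column-major order.
# Convolution weights are arrays (Cout, Cin, K) whose K slices follow the
# kernel offset table produced by conv_offsets().

conv_offsets <- function(k, nd) {
  r <- (-floor((k - 1) / 2)):(ceiling((k - 1) / 2))
  as.matrix(do.call(expand.grid, rep(list(r), nd)))
}

# He-normal initialization; caller controls the RNG stream
he_weights <- function(cout, cin, k_total, gain = 2) {
  sd <- sqrt(gain / (cin * k_total))
  array(stats::rnorm(cout * cin * k_total, sd = sd), dim = c(cout, cin, k_total))
}

conv_fwd <- function(x, w, b, offsets, dims) {
  y <- cpp_conv_fwd(x, w, offsets, as.integer(dims))
  y + b  # b recycles down columns (one bias per output channel)
}

conv_bwd <- function(dy, x, w, offsets, dims) {
  list(dx = cpp_conv_bwd_input(dy, w, offsets, as.integer(dims)),
       dw = cpp_conv_bwd_weight(dy, x, offsets, as.integer(dims)),
       db = rowSums(dy))
}

sconv_fwd <- function(x, w, b, offsets, dims, stride) {
  cpp_sconv_fwd(x, w, offsets, as.integer(dims), stride) + b
}

sconv_bwd <- function(dy, x, w, offsets, dims, stride) {
  list(dx = cpp_sconv_bwd_input(dy, w, offsets, as.integer(dims), stride),
       dw = cpp_sconv_bwd_weight(dy, x, offsets, as.integer(dims), stride),
       db = rowSums(dy))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(dy, mask) dy * mask

lrelu_fwd <- function(x, slope = 0.2) {
  mask <- x > 0
  list(y = ifelse(mask, x, slope * x), mask = mask, slope = slope)
}

lrelu_bwd <- function(dy, cache) ifelse(cache$mask, dy, cache$slope * dy)

# 2x2 max pooling (2D, even sides); returns pooled values, the winning
# quadrant per output element, and the four source-column index vectors.
pool_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]
  stopifnot(nx %% 2 == 0, ny %% 2 == 0)
  jx <- seq(1, nx, by = 2); jy <- seq(1, ny, by = 2)
  base <- outer(jx, (jy - 1) * nx, `+`)  # column of the (1,1) corner
  list(i00 = as.vector(base), i10 = as.vector(base + 1),
       i01 = as.vector(base + nx), i11 = as.vector(base + nx + 1),
       dims_out = c(nx / 2, ny / 2))
}

maxpool2_fwd <- function(x, dims) {
  pi <- pool_indices(dims)
  cand <- list(x[, pi$i00, drop = FALSE], x[, pi$i10, drop = FALSE],
               x[, pi$i01, drop = FALSE], x[, pi$i11, drop = FALSE])
  y <- cand[[1]]; sel <- matrix(1L, nrow(y), ncol(y))
  for (q in 2:4) {
    better <- cand[[q]] > y
    y[better] <- cand[[q]][better]
    sel[better] <- q
  }
  list(y = y, sel = sel, idx = pi, dims_out = pi$dims_out)
}

maxpool2_bwd <- function(dy, cache, dims) {
  dx <- matrix(0, nrow(dy), prod(dims))
  ids <- list(cache$idx$i00, cache$idx$i10, cache$idx$i01, cache$idx$i11)
  for (q in 1:4) {
    m <- cache$sel == q
    if (any(m)) dx[, ids[[q]]] <- dx[, ids[[q]]] + dy * m
  }
  dx
}

upsample_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]
  ix <- rep(seq_len(nx), each = 2)
  iy <- rep(seq_len(ny), each = 2)
  as.vector(outer(ix, (iy - 1) * nx, `+`))
}

upsample2_fwd <- function(x, dims) {
  idx <- upsample_indices(dims)
  list(y = x[, idx, drop = FALSE], idx = idx, dims_out = dims * 2)
}

upsample2_bwd <- function(dy, cache, dims) {
  # accumulate the 2x2 children of each source position (group-sum over the
  # output->input column map; every input column occurs, so rows come back
  # in order 1..N)
  t(rowsum(t(dy), group = cache$idx))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(par) {
  zeros <- lapply(par, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(par, grads, state, alpha = 5e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - alpha * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# elementwise sum of two named gradient lists
add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(a, s) lapply(a, function(g) g * s)
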