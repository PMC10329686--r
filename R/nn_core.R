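# Minimal neural-network machinery on base matrix algebra. Everything here
# is internal; reproducibility comes from seeding R's RNG before
# initialization and before any stochastic draw.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sigmoid(x)) without overflow for large |x|
log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

glorot <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l)
    list(W = glorot(sizes[l], sizes[l + 1L]), b = rep(0, sizes[l + 1L])))
}

# Forward pass; hidden layers ReLU, final layer linear (heads transform it).
# Returns the linear output and the post-activation of every layer input.
mlp_forward <- function(params, X) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% params[[l]]$W
    Z <- sweep(Z, 2L, params[[l]]$b, "+")
    H <- if (l < L) relu(Z) else Z
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

# Backprop given d(loss)/d(final linear output); returns grads mirroring params.
mlp_backward <- function(params, acts, dOut) {
  L <- length(params)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1L) delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
  }
  grads
}

# --- Adam over an arbitrary nested list of numeric arrays -------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# --- Convolution machinery (kernel 3, stride 2, zero padding 1) -------------
# Feature maps are stored as matrices: batch x (channels * h * w), each
# channel plane contiguous and column-major, matching R's array layout.

conv_geom <- function(h, w, k = 3L, s = 2L, pad = 1L) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% s + 1L
  wo <- (wp - k) %/% s + 1L
  ro <- rep(seq_len(ho), times = wo)
  co <- rep(seq_len(wo), each = ho)
  r0 <- (ro - 1L) * s                     # 0-based top-left of each patch
  c0 <- (co - 1L) * s
  IDX <- matrix(0L, ho * wo, k * k)       # linear index into a padded plane
  kk <- 0L
  for (kc in 0:(k - 1L)) for (kr in 0:(k - 1L)) {
    kk <- kk + 1L
    IDX[, kk] <- (c0 + kc) * hp + (r0 + kr + 1L)
  }
  inner <- as.integer(outer(seq_len(h) + pad,
                            (seq_len(w) + pad - 1L) * hp, `+`))
  list(h = h, w = w, hp = hp, wp = wp, ho = ho, wo = wo, k = k,
       IDX = IDX, inner = inner)
}

pad_planes <- function(X, geom, C) {
  p <- nrow(X)
  Xp <- matrix(0, p, C * geom$hp * geom$wp)
  plane_in <- geom$h * geom$w
  plane_out <- geom$hp * geom$wp
  for (c in seq_len(C))
    Xp[, (c - 1L) * plane_out + geom$inner] <-
      X[, (c - 1L) * plane_in + seq_len(plane_in), drop = FALSE]
  Xp
}

crop_planes <- function(Xp, geom, C) {
  p <- nrow(Xp)
  plane_in <- geom$h * geom$w
  plane_out <- geom$hp * geom$wp
  X <- matrix(0, p, C * plane_in)
  for (c in seq_len(C))
    X[, (c - 1L) * plane_in + seq_len(plane_in)] <-
      Xp[, (c - 1L) * plane_out + geom$inner, drop = FALSE]
  X
}

# Patches matrix: (batch * ho * wo) x (k*k*Cin); row order batch-fastest.
im2col <- function(Xp, geom, C) {
  p <- nrow(Xp)
  kk <- geom$k * geom$k
  P <- matrix(0, p * geom$ho * geom$wo, kk * C)
  plane <- geom$hp * geom$wp
  for (c in seq_len(C)) for (q in seq_len(kk))
    P[, (c - 1L) * kk + q] <- as.vector(Xp[, (c - 1L) * plane + geom$IDX[, q]])
  P
}

# Scatter-add of a patches matrix back into padded planes (adjoint of im2col).
col2im <- function(P, geom, C, p) {
  kk <- geom$k * geom$k
  plane <- geom$hp * geom$wp
  npos <- geom$ho * geom$wo
  Xp <- matrix(0, p, C * plane)
  for (c in seq_len(C)) for (q in seq_len(kk)) {
    idx <- (c - 1L) * plane + geom$IDX[, q]   # unique within one q (stride 2)
    Xp[, idx] <- Xp[, idx] + matrix(P[, (c - 1L) * kk + q], p, npos)
  }
  Xp
}

# W: (k*k*Cin) x Cout, b: length Cout. Returns output + cache for backward.
conv_forward <- function(X, W, b, geom, Cin, Cout) {
  p <- nrow(X)
  P <- im2col(pad_planes(X, geom, Cin), geom, Cin)
  Z <- P %*% W
  Z <- sweep(Z, 2L, b, "+")
  list(out = matrix(Z, p, Cout * geom$ho * geom$wo), P = P)
}

conv_backward <- function(dOut, cache, W, geom, Cin, Cout) {
  p <- nrow(dOut)
  dZ <- matrix(dOut, p * geom$ho * geom$wo, Cout)
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dXp <- col2im(dZ %*% t(W), geom, Cin, p)
  list(dX = crop_planes(dXp, geom, Cin), dW = dW, db = db)
}

# Transposed convolution: upsamples (h, w) -> (2h, 2w) using the geometry of
# the stride-2 conv from the big plane down to the small one (the forward
# pass is that conv's adjoint). W: (k*k*Cout) x Cin, b: length Cout.
deconv_forward <- function(U, W, b, geom_big, Cin, Cout) {
  p <- nrow(U)
  Um <- matrix(U, p * geom_big$ho * geom_big$wo, Cin)
  Yp <- col2im(Um %*% t(W), geom_big, Cout, p)
  Y <- crop_planes(Yp, geom_big, Cout)
  plane <- geom_big$h * geom_big$w
  for (c in seq_len(Cout))
    Y[, (c - 1L) * plane + seq_len(plane)] <-
      Y[, (c - 1L) * plane + seq_len(plane)] + b[c]
  list(out = Y, Um = Um)
}

deconv_backward <- function(dY, cache, W, geom_big, Cin, Cout) {
  p <- nrow(dY)
  P <- im2col(pad_planes(dY, geom_big, Cout), geom_big, Cout)
  dU <- matrix(P %*% W, p, Cin * geom_big$ho * geom_big$wo)
  dW <- crossprod(P, cache$Um)
  plane <- geom_big$h * geom_big$w
  db <- vapply(seq_len(Cout), function(c)
    sum(dY[, (c - 1L) * plane + seq_len(plane)]), numeric(1))
  list(dU = dU, dW = dW, db = db)
}
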