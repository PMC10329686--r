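#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'  (1/2) sum_d (sigma_d^2 + mu_d^2 - 1 - log sigma_d^2)`.
#'
#' @param mu numeric vector (embedding mean).
#' @param sigma numeric vector of the same length, strictly positive.
#' @return Non-negative scalar; 0 iff `mu = 0` and `sigma = 1`.
#' @export
kl_divergence <- function(mu, sigma) {
  if (length(mu) != length(sigma))
    stop("mu and sigma must have the same length", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  0.5 * sum(sigma^2 + mu^2 - 1 - 2 * log(sigma))
}

#' Decompose the augmenter objective into reconstruction and KL parts
#'
#' `total = recon + beta * kl` where `recon` is the squared reconstruction
#' error summed over occupied spot positions (and genes) only, and `kl` is
#' the sum over genes of the per-gene embedding KL term. (The KL enters
#' once per gene, matching the per-gene posterior, not once per spot.)
#'
#' @param X,X_hat image arrays of identical shape (`p x n1 x n2`, or any
#'   matching arrays); `X_hat` is the decoder reconstruction.
#' @param mu,sigma per-gene posterior parameters: `p x D` matrices (or
#'   vectors for a single gene).
#' @param beta KL weight (default 1e-5).
#' @param mask optional logical array over the spatial positions of one
#'   image (`n1 x n2`); defaults to all positions occupied.
#' @return List with `total`, `recon`, `kl` (`total == recon + beta * kl`).
#' @export
augmenter_loss <- function(X, X_hat, mu, sigma, beta = 1e-5, mask = NULL) {
  if (!identical(dim(X), dim(X_hat)) || is.null(dim(X)) != is.null(dim(X_hat)))
    stop("X and X_hat must have identical shape", call. = FALSE)
  d2 <- (X - X_hat)^2
  recon <- if (is.null(mask)) sum(d2) else {
    stopifnot(length(dim(X)) == 3L, identical(dim(mask), dim(X)[2:3]))
    occ <- which(mask)
    p <- dim(X)[1L]
    sum(vapply(seq_len(p), function(j) sum(d2[j + (occ - 1L) * p]), numeric(1)))
  }
  mu <- rbind(mu); sigma <- rbind(sigma)
  kl <- sum(vapply(seq_len(nrow(mu)), function(j)
    kl_divergence(mu[j, ], sigma[j, ]), numeric(1)))
  list(total = recon + beta * kl, recon = recon, kl = kl)
}

#' Configuration for the augmentation VAE
#'
#' Encoder: three stride-2 3x3 convolution layers with 16, 8 and 4 channels
#' followed by a fully connected layer producing the embedding mean and
#' log-SD. Decoder mirrors it (channels 4, 8, 16), taking the sampled
#' embedding concatenated with the gene's one-hot cluster indicator.
#'
#' @param embedding_dim embedding dimension `D` (default 512).
#' @param beta KL weight (default 1e-5, chosen so the two loss components
#'   have similar magnitude).
#' @param epochs training epochs (default 500).
#' @param lr Adam learning rate (default 1e-3).
#' @return An `AugmenterConfig` list.
#' @export
augmenter_config <- function(embedding_dim = 512L, beta = 1e-5,
                             epochs = 500L, lr = 1e-3) {
  stopifnot(embedding_dim >= 1L, beta >= 0, epochs >= 1L)
  structure(list(embedding_dim = as.integer(embedding_dim), beta = beta,
                 epochs = as.integer(epochs), lr = lr,
                 channels = c(16L, 8L, 4L)),
            class = "AugmenterConfig")
}

# pad a stack's images up to conv-friendly (multiple of 8) height/width;
# returns batch matrix p x (H*W) plus the occupied linear positions
.vae_geometry <- function(stack) {
  H <- 8L * ((stack$n1 + 7L) %/% 8L)
  W <- 8L * ((stack$n2 + 7L) %/% 8L)
  p <- length(stack$gene_ids)
  Xb <- matrix(0, p, H * W)
  lin_img <- (stack$coord_index$col - 1L) * stack$n1 + stack$coord_index$row
  lin_pad <- (stack$coord_index$col - 1L) * H + stack$coord_index$row
  for (j in seq_len(p)) Xb[j, lin_pad] <- stack$images[j + (lin_img - 1L) * p]
  occ <- rep(0, H * W); occ[lin_pad] <- 1
  list(H = H, W = W, Xb = Xb, occ = occ, lin_pad = lin_pad)
}

.vae_forward <- function(pars, Xb, onehot, geoms, eps) {
  g1 <- geoms$g1; g2 <- geoms$g2; g3 <- geoms$g3
  c1 <- conv_forward(Xb, pars$W1, pars$b1, g1, 1L, 16L);  h1 <- relu(c1$out)
  c2 <- conv_forward(h1, pars$W2, pars$b2, g2, 16L, 8L);  h2 <- relu(c2$out)
  c3 <- conv_forward(h2, pars$W3, pars$b3, g3, 8L, 4L);   h3 <- relu(c3$out)
  mu <- sweep(h3 %*% pars$Wm, 2L, pars$bm, "+")
  logsig <- sweep(h3 %*% pars$Ws, 2L, pars$bs, "+")
  sig <- exp(logsig)
  z <- mu + sig * eps
  zc <- cbind(z, onehot)
  f <- sweep(zc %*% pars$Wd, 2L, pars$bd, "+"); g <- relu(f)
  d1 <- deconv_forward(g, pars$V1, pars$c1, g3, 4L, 8L);  u1 <- relu(d1$out)
  d2 <- deconv_forward(u1, pars$V2, pars$c2, g2, 8L, 16L); u2 <- relu(d2$out)
  d3 <- deconv_forward(u2, pars$V3, pars$c3, g1, 16L, 1L)
  list(Xhat = d3$out, mu = mu, logsig = logsig, sig = sig, z = z, zc = zc,
       c1 = c1, c2 = c2, c3 = c3, h1 = h1, h2 = h2, h3 = h3,
       f = f, g = g, d1 = d1, d2 = d2, d3 = d3, eps = eps)
}

.vae_backward <- function(pars, fw, Xb, occ_mat, beta, geoms) {
  g1 <- geoms$g1; g2 <- geoms$g2; g3 <- geoms$g3
  dXhat <- 2 * (fw$Xhat - Xb) * occ_mat
  b3 <- deconv_backward(dXhat, fw$d3, pars$V3, g1, 16L, 1L)
  du2 <- b3$dU * (fw$d2$out > 0)
  b2 <- deconv_backward(du2, fw$d2, pars$V2, g2, 8L, 16L)
  du1 <- b2$dU * (fw$d1$out > 0)
  b1 <- deconv_backward(du1, fw$d1, pars$V1, g3, 4L, 8L)
  dg <- b1$dU
  df <- dg * (fw$f > 0)
  dWd <- crossprod(fw$zc, df); dbd <- colSums(df)
  dzc <- df %*% t(pars$Wd)
  D <- ncol(fw$mu)
  dz <- dzc[, seq_len(D), drop = FALSE]
  dmu <- dz + beta * fw$mu
  dlogsig <- dz * fw$eps * fw$sig + beta * (fw$sig^2 - 1)
  dWm <- crossprod(fw$h3, dmu); dbm <- colSums(dmu)
  dWs <- crossprod(fw$h3, dlogsig); dbs <- colSums(dlogsig)
  dh3 <- (dmu %*% t(pars$Wm) + dlogsig %*% t(pars$Ws)) * (fw$c3$out > 0)
  e3 <- conv_backward(dh3, fw$c3, pars$W3, g3, 8L, 4L)
  dh2 <- e3$dX * (fw$c2$out > 0)
  e2 <- conv_backward(dh2, fw$c2, pars$W2, g2, 16L, 8L)
  dh1 <- e2$dX * (fw$c1$out > 0)
  e1 <- conv_backward(dh1, fw$c1, pars$W1, g1, 1L, 16L)
  list(W1 = e1$dW, b1 = e1$db, W2 = e2$dW, b2 = e2$db, W3 = e3$dW, b3 = e3$db,
       Wm = dWm, bm = dbm, Ws = dWs, bs = dbs, Wd = dWd, bd = dbd,
       V1 = b1$dW, c1 = b1$db, V2 = b2$dW, c2 = b2$db, V3 = b3$dW, c3 = b3$db)
}

#' Fit the cluster-conditioned variational autoencoder on gene images
#'
#' Each gene's rasterized 2D expression map is one training sample. The
#' encoder summarizes it into a per-gene Gaussian embedding posterior
#' `(mu_j, sigma_j)`; the decoder reconstructs the map from a sampled
#' embedding concatenated with the gene's one-hot cluster indicator. The
#' objective is squared reconstruction error over occupied spot positions
#' plus `beta` times the per-gene KL divergence to the standard normal.
#'
#' @param stack a `GeneImageStack` from [rasterize_genes()].
#' @param clusters a `GeneClusterAssignment` over the same genes.
#' @param config an [augmenter_config()].
#' @param seed RNG seed; training is deterministic given the seed.
#' @return An `AugmenterModel` carrying the network parameters, per-gene
#'   posterior (`mu`, `sigma`), the training trajectory (`$log`, columns
#'   epoch/total/recon/kl), and `converged` — `FALSE` (with a message, not
#'   an error) when the final loss failed to improve on the initial one.
#' @export
train_augmenter <- function(stack, clusters, config = augmenter_config(),
                            seed = 1L) {
  stopifnot(inherits(stack, "GeneImageStack"),
            inherits(clusters, "GeneClusterAssignment"),
            inherits(config, "AugmenterConfig"))
  p <- length(stack$gene_ids)
  if (nrow(clusters$one_hot) != p)
    stop("cluster assignment does not cover the stack's genes", call. = FALSE)
  geo <- .vae_geometry(stack)
  H <- geo$H; W <- geo$W
  g1 <- conv_geom(H, W); g2 <- conv_geom(H / 2L, W / 2L); g3 <- conv_geom(H / 4L, W / 4L)
  geoms <- list(g1 = g1, g2 = g2, g3 = g3)
  Fdim <- 4L * (H / 8L) * (W / 8L)
  D <- config$embedding_dim; K <- clusters$K

  set.seed(seed)
  pars <- list(
    W1 = glorot(9L, 16L),        b1 = rep(0, 16L),
    W2 = glorot(9L * 16L, 8L),   b2 = rep(0, 8L),
    W3 = glorot(9L * 8L, 4L),    b3 = rep(0, 4L),
    Wm = glorot(Fdim, D),        bm = rep(0, D),
    Ws = glorot(Fdim, D),        bs = rep(-2, D),   # start with small sigma
    Wd = glorot(D + K, Fdim),    bd = rep(0, Fdim),
    V1 = glorot(9L * 8L, 4L),    c1 = rep(0, 8L),
    V2 = glorot(9L * 16L, 8L),   c2 = rep(0, 16L),
    V3 = glorot(9L * 1L, 16L),   c3 = rep(0, 1L))
  st <- adam_init(pars)
  occ_mat <- matrix(geo$occ, p, H * W, byrow = TRUE)
  onehot <- clusters$one_hot

  log <- data.frame(epoch = integer(0), total = numeric(0),
                    recon = numeric(0), kl = numeric(0))
  for (ep in seq_len(config$epochs)) {
    eps <- matrix(rnorm(p * D), p, D)
    fw <- .vae_forward(pars, geo$Xb, onehot, geoms, eps)
    recon <- sum(((fw$Xhat - geo$Xb)^2) * occ_mat)
    kl <- 0.5 * sum(fw$sig^2 + fw$mu^2 - 1 - 2 * fw$logsig)
    log <- rbind(log, data.frame(epoch = ep, total = recon + config$beta * kl,
                                 recon = recon, kl = kl))
    gr <- .vae_backward(pars, fw, geo$Xb, occ_mat, config$beta, geoms)
    upd <- adam_step(pars, gr, st, lr = config$lr)
    pars <- upd$params; st <- upd$state
  }

  # posterior without sampling noise for downstream generation
  fw <- .vae_forward(pars, geo$Xb, onehot, geoms, matrix(0, p, D))
  converged <- tail(log$total, 1L) < log$total[1L]
  if (!converged)
    message("augmenter did not improve on its initial loss after ",
            config$epochs, " epochs; model returned with converged = FALSE")
  structure(list(pars = pars, config = config, geoms = geoms,
                 H = H, W = W, D = D, K = K,
                 mu = fw$mu, sigma = fw$sig,
                 gene_ids = stack$gene_ids, log = log,
                 kl_convention = "one KL term per gene",
                 converged = converged, seed = seed, trained = TRUE),
            class = "AugmenterModel")
}

#' @export
print.AugmenterModel <- function(x, ...) {
  cat(sprintf("AugmenterModel: %d genes, %dx%d padded grid, D = %d, K = %d\n",
              length(x$gene_ids), x$H, x$W, x$D, x$K))
  cat(sprintf("  %d epochs, final loss %.4g (%s)%s\n", nrow(x$log),
              tail(x$log$total, 1L), x$kl_convention,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Sample artificial ST replicates from a trained augmenter
#'
#' For every replicate and gene, an embedding is drawn from the gene's
#' fitted posterior `N(mu_j, sigma_j^2)`, decoded with the gene's cluster
#' one-hot, and read back at the occupied grid positions into spot-vector
#' form, so each replicate aligns row-for-row and column-for-column with
#' the source reference. Two replicates generally balance original and
#' fabricated information best, hence `R = 2` by default.
#'
#' @param model a trained `AugmenterModel`.
#' @param stack the `GeneImageStack` the model was fitted on.
#' @param clusters the matching `GeneClusterAssignment`.
#' @param R number of replicates (default 2).
#' @param seed RNG seed for the embedding draws.
#' @return A `ReplicateSet`: list of `R` matrices (`n_spots x p`), the
#'   source fingerprint, and the seed.
#' @export
generate_replicates <- function(model, stack, clusters, R = 2L, seed = 1L) {
  if (!inherits(model, "AugmenterModel") || !isTRUE(model$trained))
    stop("model is not a trained AugmenterModel", call. = FALSE)
  stopifnot(R >= 1L)
  if (!identical(model$gene_ids, stack$gene_ids))
    stop("stack genes do not match the trained model", call. = FALSE)
  geo <- .vae_geometry(stack)
  p <- length(stack$gene_ids)
  set.seed(seed)
  reps <- lapply(seq_len(R), function(r) {
    eps <- matrix(rnorm(p * model$D), p, model$D)
    z <- model$mu + model$sigma * eps
    Xhat <- .vae_decode(model$pars, cbind(z, clusters$one_hot), model$geoms)
    out <- t(Xhat[, geo$lin_pad, drop = FALSE])    # n_spots x p
    dimnames(out) <- list(stack$coord_index$spot, stack$gene_ids)
    out
  })
  structure(list(replicates = reps,
                 source_fingerprint = sprintf("%dx%d:%.6g", nrow(stack$S), p,
                                              sum(stack$images)),
                 seed = seed),
            class = "ReplicateSet")
}

.vae_decode <- function(pars, zc, geoms) {
  g <- relu(sweep(zc %*% pars$Wd, 2L, pars$bd, "+"))
  u1 <- relu(deconv_forward(g, pars$V1, pars$c1, geoms$g3, 4L, 8L)$out)
  u2 <- relu(deconv_forward(u1, pars$V2, pars$c2, geoms$g2, 8L, 16L)$out)
  deconv_forward(u2, pars$V3, pars$c3, geoms$g1, 16L, 1L)$out
}

#' @export
print.ReplicateSet <- function(x, ...) {
  cat(sprintf("ReplicateSet: %d replicate(s) of %s (seed %d)\n",
              length(x$replicates), x$source_fingerprint, x$seed))
  invisible(x)
}
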