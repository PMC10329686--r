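# Independent brute-force oracles. These deliberately use plain loops and
# direct formulas so they share no code path with the package internals.

naive_coord_loss <- function(pred, truth) {
  s <- 0
  for (i in seq_len(nrow(pred)))
    s <- s + (truth[i, 1] - pred[i, 1])^2 + (truth[i, 2] - pred[i, 2])^2
  s
}

naive_ellipse_loss <- function(pred, truth, alpha) {
  s <- 0
  for (i in seq_len(nrow(pred))) {
    q <- ((truth[i, 1] - pred[i, 1]) / pred[i, 3])^2 +
         ((truth[i, 2] - pred[i, 2]) / pred[i, 4])^2
    si <- if (q <= 1) 1 else 0
    s <- s + (alpha * (1 - si) + (1 - alpha) * si) * abs(q - 1)
  }
  s
}

naive_domain_loss <- function(scores, labels, C) {
  sg <- function(x) exp(x) / (1 + exp(x))
  s <- 0
  for (i in seq_len(nrow(scores))) for (c in seq_len(C)) {
    if (labels[i] == c) s <- s - log(sg(scores[i, c]))
    else s <- s - log(1 - sg(scores[i, c]))
  }
  s
}

naive_ordinal_loss <- function(a, b, labels, L) {
  sg <- function(x) exp(x) / (1 + exp(x))
  s <- 0
  for (i in seq_along(a)) for (l in seq_len(L - 1)) {
    if (labels[i] > l) s <- s - log(sg(a[i] + b[l]))
    else s <- s - log(1 - sg(a[i] + b[l]))
  }
  s
}

naive_kl <- function(mu, sigma) {
  s <- 0
  for (d in seq_along(mu))
    s <- s + sigma[d]^2 + mu[d]^2 - 1 - log(sigma[d]^2)
  s / 2
}

# Monte-Carlo KL(N(mu, sigma^2) || N(0, 1)) with standard error
mc_kl <- function(mu, sigma, n = 1e6) {
  x <- rnorm(n, mu, sigma)
  ll <- dnorm(x, mu, sigma, log = TRUE) - dnorm(x, log = TRUE)
  c(est = mean(ll), se = sd(ll) / sqrt(n))
}

naive_augmenter_loss <- function(X, X_hat, mu, sigma, beta, mask) {
  p <- dim(X)[1]
  recon <- 0
  for (j in seq_len(p)) for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) recon <- recon + (X[j, r, c] - X_hat[j, r, c])^2
  kl <- 0
  for (j in seq_len(p)) kl <- kl + naive_kl(mu[j, ], sigma[j, ])
  list(total = recon + beta * kl, recon = recon, kl = kl)
}

# clipped-window SSIM by direct looping, population variance, matching the
# documented constants
naive_ssim <- function(a, b, window = 7, K1 = 0.01, K2 = 0.03) {
  valid <- !is.na(a) & !is.na(b)
  rng <- max(c(a[valid], b[valid])) - min(c(a[valid], b[valid]))
  C1 <- (K1 * rng)^2; C2 <- (K2 * rng)^2
  half <- (window - 1) %/% 2
  vals <- c()
  for (r in seq_len(nrow(a))) for (cc in seq_len(ncol(a))) {
    rs <- max(1, r - half):min(nrow(a), r + half)
    cs <- max(1, cc - half):min(ncol(a), cc + half)
    wa <- a[rs, cs]; wb <- b[rs, cs]; wv <- valid[rs, cs]
    if (!any(wv)) next
    xa <- wa[wv]; xb <- wb[wv]
    ma <- mean(xa); mb <- mean(xb)
    va <- mean(xa^2) - ma^2; vb <- mean(xb^2) - mb^2
    cab <- mean(xa * xb) - ma * mb
    vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                    ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  idx <- sum(choose(tab, 2))
  n <- sum(tab)
  expected <- a * b / choose(n, 2)
  mx <- (a + b) / 2
  (idx - expected) / (mx - expected)
}

# --- shared small fixtures --------------------------------------------------

tiny_spots <- function(n1 = 6, n2 = 6, genes = NULL, seed = 11,
                       hole_fraction = 0, n_layers = 2) {
  genes <- genes %||% {
    g <- list(a = linear_gradient(0, 2), b = linear_gradient(pi / 2, 2),
              c = layer_marker(1, 2), d = null_gene())
    g
  }
  make_reference(tissue_spec(grid = c(n1, n2), hole_fraction = hole_fraction,
                             n_layers = n_layers, genes = genes, seed = seed))
}

gradient_panel <- function(n_grad = 12, n_null = 4, seed = 1) {
  set.seed(seed)
  g <- list()
  for (j in seq_len(n_grad))
    g[[sprintf("grad%02d", j)]] <- linear_gradient(runif(1, 0, 2 * pi), 2)
  for (j in seq_len(n_null)) g[[sprintf("null%02d", j)]] <- null_gene()
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
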