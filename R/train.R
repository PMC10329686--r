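#' Configuration for the location predictor
#'
#' @param task one of `"coord2d"`, `"ellipse"`, `"domain"`, `"ordinal"`.
#' @param hidden_sizes sizes of the ReLU hidden layers; default `c(50, 10, 5)`.
#' @param alpha target coverage of the elliptical region (ellipse task only);
#'   default 0.95.
#' @param n_classes number of domains `C` (domain) or layers `L` (ordinal);
#'   inferred from the reference's label set when `NULL`.
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 500).
#' @param batch_size minibatch size; `NULL` means full batch below 5000 rows,
#'   1024 otherwise. Minibatch gradients are rescaled by `n / batch_size` so
#'   the summed-loss objective is comparable across batch sizes.
#' @param seed integer RNG seed controlling initialization and batching.
#' @return A `LocationModelConfig` list.
#' @export
location_model_config <- function(task = c("coord2d", "ellipse", "domain", "ordinal"),
                                  hidden_sizes = c(50L, 10L, 5L),
                                  alpha = 0.95, n_classes = NULL,
                                  lr = 1e-3, epochs = 500L,
                                  batch_size = NULL, seed = 1L) {
  task <- match.arg(task)
  hidden_sizes <- as.integer(hidden_sizes)
  if (!length(hidden_sizes) || any(hidden_sizes <= 0L))
    stop("hidden_sizes must be a non-empty vector of positive integers",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(n_classes) && n_classes < 2L)
    stop("n_classes must be >= 2", call. = FALSE)
  structure(list(task = task, hidden_sizes = hidden_sizes, alpha = alpha,
                 n_classes = n_classes, lr = lr, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "LocationModelConfig")
}

# cut points b from unconstrained theta: b_1 = theta_1, then subtract
# softplus increments so b is non-increasing by construction
.theta_to_b <- function(theta) {
  if (length(theta) == 1L) return(theta)
  theta[1L] - cumsum(c(0, softplus(theta[-1L])))
}

# head-specific loss and gradient wrt the final linear output (and theta)
.head_loss_grad <- function(task, Z, y, alpha, theta = NULL, L = NULL) {
  if (task == "coord2d") {
    yhat <- sigmoid(Z)
    loss <- coord_loss(yhat, y)
    dZ <- 2 * (yhat - y) * yhat * (1 - yhat)
    return(list(loss = loss, dZ = dZ))
  }
  if (task == "ellipse") {
    cen <- sigmoid(Z[, 1:2, drop = FALSE])
    r <- softplus(Z[, 3:4, drop = FALSE]) + 1e-6
    d1 <- y[, 1L] - cen[, 1L]; d2 <- y[, 2L] - cen[, 2L]
    q <- (d1 / r[, 1L])^2 + (d2 / r[, 2L])^2
    s <- as.numeric(q <= 1)
    w <- alpha * (1 - s) + (1 - alpha) * s
    loss <- sum(w * abs(q - 1))
    dq <- w * sign(q - 1)
    dc1 <- dq * (-2 * d1 / r[, 1L]^2); dc2 <- dq * (-2 * d2 / r[, 2L]^2)
    dr1 <- dq * (-2 * d1^2 / r[, 1L]^3); dr2 <- dq * (-2 * d2^2 / r[, 2L]^3)
    dZ <- cbind(dc1 * cen[, 1L] * (1 - cen[, 1L]),
                dc2 * cen[, 2L] * (1 - cen[, 2L]),
                dr1 * sigmoid(Z[, 3L]), dr2 * sigmoid(Z[, 4L]))
    return(list(loss = loss, dZ = dZ))
  }
  if (task == "domain") {
    C <- ncol(Z)
    Y <- matrix(0, nrow(Z), C)
    Y[cbind(seq_len(nrow(Z)), y)] <- 1
    loss <- domain_loss(Z, y, C)
    return(list(loss = loss, dZ = sigmoid(Z) - Y))
  }
  # ordinal: Z is n x 1 score, theta parameterizes the cut points
  b <- .theta_to_b(theta)
  a <- drop(Z)
  loss <- ordinal_loss(a, b, y, L)
  S <- sigmoid(outer(a, b, `+`))
  G <- outer(y, seq_len(L - 1L), `>`) * 1
  E <- S - G                                    # n x (L-1)
  dZ <- matrix(rowSums(E), ncol = 1L)
  db <- colSums(E)
  dtheta <- numeric(length(theta))
  dtheta[1L] <- sum(db)
  if (length(theta) > 1L)
    for (j in 2:length(theta))
      dtheta[j] <- -sigmoid(theta[j]) * sum(db[j - 1L + seq_len(L - j)])
  list(loss = loss, dZ = dZ, dtheta = dtheta)
}

.head_dim <- function(task, n_classes)
  switch(task, coord2d = 2L, ellipse = 4L, domain = n_classes, ordinal = 1L)

#' Train the supervised location predictor
#'
#' Fits a feed-forward network (ReLU hidden layers, default sizes 50/10/5)
#' from normalized expression to the task target: scaled 2D coordinates
#' (`coord2d`, sigmoid outputs), an elliptical prediction region
#' (`ellipse`, sigmoid centers + softplus semi-axes), unordered domains
#' (`domain`, one-vs-rest logistic) or ordered layers (`ordinal`, one
#' shared score plus monotone cut points). Optimization is Adam on the
#' summed loss; the loss trajectory is recorded in `$log`.
#'
#' @param reference a normalized `SpotExpression` with `spatial_coords`
#'   (coord2d/ellipse) or labels (domain/ordinal).
#' @param replicates optional `ReplicateSet` from [generate_replicates()];
#'   replicate rows are appended to the training matrix and reuse their
#'   source spot's coordinates and labels.
#' @param config a [location_model_config()].
#' @return A `LocationModel` (network parameters, task, feature gene list,
#'   coordinate scaler, label order, training log).
#' @export
train_location_model <- function(reference, replicates = NULL,
                                 config = location_model_config()) {
  stopifnot(is_spot(reference), inherits(config, "LocationModelConfig"))
  if (!reference$normalized)
    stop("reference must be normalized before training", call. = FALSE)
  task <- config$task
  X <- reference$matrix
  n0 <- nrow(X)

  scaler <- NULL; y <- NULL; label_set <- NULL; L <- NULL
  if (task %in% c("coord2d", "ellipse")) {
    if (is.null(reference$spatial_coords))
      stop("task '", task, "' needs spatial_coords", call. = FALSE)
    scaler <- fit_coord_scaler(reference$spatial_coords)
    y <- scale_coords(reference$spatial_coords, scaler)
  } else {
    if (is.null(reference$labels))
      stop("task '", task, "' needs per-spot labels", call. = FALSE)
    label_set <- reference$label_set
    L <- config$n_classes %||% length(label_set)
    if (L != length(label_set))
      stop("n_classes (", L, ") does not match the label set (",
           length(label_set), ")", call. = FALSE)
    y <- match(reference$labels, label_set)
  }

  if (!is.null(replicates)) {
    stopifnot(inherits(replicates, "ReplicateSet"))
    for (rep_m in replicates$replicates) {
      if (!identical(dim(rep_m), dim(reference$matrix)))
        stop("replicate shape does not match the reference", call. = FALSE)
      X <- rbind(X, rep_m)
      y <- if (is.matrix(y)) rbind(y, y[seq_len(n0), , drop = FALSE]) else c(y, y[seq_len(n0)])
    }
  }

  n <- nrow(X)
  sizes <- c(ncol(X), config$hidden_sizes, .head_dim(task, L))
  set.seed(config$seed)
  params <- mlp_init(sizes)
  theta <- if (task == "ordinal") rnorm(L - 1L, sd = 0.1) else NULL
  st <- adam_init(params)
  st_theta <- if (task == "ordinal") list(m = theta * 0, v = theta * 0, t = 0L)
  batch <- config$batch_size %||% if (n <= 5000L) n else 1024L
  log <- data.frame(epoch = integer(0), loss = numeric(0))

  for (ep in seq_len(config$epochs)) {
    idx_all <- if (batch >= n) list(seq_len(n)) else {
      perm <- sample.int(n)
      split(perm, ceiling(seq_along(perm) / batch))
    }
    ep_loss <- 0
    for (idx in idx_all) {
      fw <- mlp_forward(params, X[idx, , drop = FALSE])
      hd <- .head_loss_grad(task, fw$out,
                            if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx],
                            config$alpha, theta, L)
      ep_loss <- ep_loss + hd$loss
      scale <- n / length(idx)   # summed loss: keep gradients batch-comparable
      grads <- mlp_backward(params, fw$acts, hd$dZ * scale)
      upd <- adam_step(params, grads, st, lr = config$lr)
      params <- upd$params; st <- upd$state
      if (task == "ordinal") {
        g <- hd$dtheta * scale
        st_theta$t <- st_theta$t + 1L
        st_theta$m <- 0.9 * st_theta$m + 0.1 * g
        st_theta$v <- 0.999 * st_theta$v + 0.001 * g * g
        mh <- st_theta$m / (1 - 0.9^st_theta$t)
        vh <- st_theta$v / (1 - 0.999^st_theta$t)
        theta <- theta - config$lr * mh / (sqrt(vh) + 1e-8)
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss))
  }

  structure(list(params = params, theta = theta, task = task,
                 config = config, feature_genes = reference$gene_ids,
                 scaler = scaler, label_set = label_set, n_classes = L,
                 log = log, n_train = n,
                 version = as.character(packageVersion("spotloc"))),
            class = "LocationModel")
}

#' @export
print.LocationModel <- function(x, ...) {
  cat(sprintf("LocationModel (%s): %d features -> [%s] -> %d output(s)\n",
              x$task, length(x$feature_genes),
              paste(x$config$hidden_sizes, collapse = ", "),
              .head_dim(x$task, x$n_classes)))
  cat(sprintf("  trained on %d rows, %d epochs; final loss %.4g\n",
              x$n_train, nrow(x$log), tail(x$log$loss, 1L)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
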