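# The four task losses. All are SUMS over the batch, as the model is
# defined; training keeps the summed form and rescales minibatch gradients
# for comparability across batch sizes.

#' Summed squared-error loss for 2D coordinate recovery
#'
#' `sum_i [(y_i1 - yhat_i1)^2 + (y_i2 - yhat_i2)^2]`, both sets of
#' coordinates living in the unit square after [scale_coords()].
#'
#' @param pred_coords,true_coords numeric `n x 2` matrices.
#' @return Non-negative scalar.
#' @export
coord_loss <- function(pred_coords, true_coords) {
  pred_coords <- as.matrix(pred_coords); true_coords <- as.matrix(true_coords)
  if (!identical(dim(pred_coords), dim(true_coords)))
    stop("prediction/truth length mismatch", call. = FALSE)
  sum((true_coords - pred_coords)^2)
}

#' Asymmetric quantile-style loss for elliptical prediction regions
#'
#' Each prediction is an axis-aligned ellipse (center `c1, c2`, semi-axes
#' `r1, r2 > 0`). With the normalized squared radius
#' `q_i = ((y_i1-c_i1)/r_i1)^2 + ((y_i2-c_i2)/r_i2)^2` and coverage
#' indicator `s_i = I(q_i <= 1)`, each point contributes
#' `(alpha (1 - s_i) + (1 - alpha) s_i) * |q_i - 1|`: misses are penalized
#' with weight `alpha`, covered points with weight `1 - alpha`, so the
#' fitted ellipse approximates an `alpha`-coverage region.
#'
#' @param pred numeric `n x 4` matrix, columns `c1, c2, r1, r2`.
#' @param true_coords numeric `n x 2` matrix.
#' @param alpha target coverage in (0, 1).
#' @return Non-negative scalar.
#' @export
ellipse_loss <- function(pred, true_coords, alpha) {
  pred <- as.matrix(pred); true_coords <- as.matrix(true_coords)
  stopifnot(ncol(pred) == 4L, ncol(true_coords) == 2L,
            nrow(pred) == nrow(true_coords))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(pred[, 3:4] <= 0))
    stop("ellipse semi-axes must be strictly positive", call. = FALSE)
  q <- ((true_coords[, 1L] - pred[, 1L]) / pred[, 3L])^2 +
       ((true_coords[, 2L] - pred[, 2L]) / pred[, 4L])^2
  s <- as.numeric(q <= 1)
  sum((alpha * (1 - s) + (1 - alpha) * s) * abs(q - 1))
}

#' One-vs-rest logistic loss for spatial-domain recovery
#'
#' Labeled binary cross-entropy over `C` class scores per unit:
#' `-sum_i sum_c [ I(y_i = c) log sigma(a_ic) + I(y_i != c) log(1 - sigma(a_ic)) ]`.
#'
#' @param scores numeric `n x C` matrix of raw class scores.
#' @param labels integer labels in `1..C`.
#' @param C number of domains.
#' @return Non-negative scalar (numerically stabilized).
#' @export
domain_loss <- function(scores, labels, C) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == C, nrow(scores) == length(labels))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > C))
    stop("labels must lie in 1..C", call. = FALSE)
  Y <- matrix(0, nrow(scores), C)
  Y[cbind(seq_len(nrow(scores)), labels)] <- 1
  # log sigma(a) = log_sigmoid(a); log(1 - sigma(a)) = log_sigmoid(-a)
  -sum(Y * log_sigmoid(scores) + (1 - Y) * log_sigmoid(-scores))
}

#' Rank-consistent ordinal (cumulative logit) loss for layered tissue
#'
#' One score `a_i` per unit is shared across `L - 1` thresholds with cut
#' points `b_1..b_{L-1}`:
#' `-sum_i sum_l [ log sigma(a_i + b_l) I(y_i > l) + log(1 - sigma(a_i + b_l)) (1 - I(y_i > l)) ]`.
#' With non-increasing `b`, `P(y > l) = sigma(a + b_l)` is monotone in `l`
#' and the implied per-layer probabilities are valid.
#'
#' @param a numeric vector of per-unit scores.
#' @param b numeric vector of `L - 1` cut points.
#' @param labels integer layer indices in `1..L`.
#' @param L number of ordered layers.
#' @return Non-negative scalar.
#' @export
ordinal_loss <- function(a, b, labels, L) {
  stopifnot(length(b) == L - 1L, length(a) == length(labels))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > L))
    stop("labels must lie in 1..L", call. = FALSE)
  Z <- outer(a, b, `+`)                         # n x (L-1)
  G <- outer(labels, seq_len(L - 1L), `>`) * 1  # I(y_i > l)
  -sum(G * log_sigmoid(Z) + (1 - G) * log_sigmoid(-Z))
}

#' Per-layer probabilities implied by the cumulative ordinal construction
#'
#' `P(y > l) = sigma(a + b_l)`; differencing the survival curve gives the
#' layer masses. Requires non-increasing cut points `b` so that the masses
#' are non-negative.
#'
#' @param a score(s): scalar or length-n vector.
#' @param b non-increasing cut points, length `L - 1`.
#' @param L number of layers.
#' @param strict error (TRUE, default) or warn on unordered `b`.
#' @return `n x L` matrix of probabilities (rows sum to 1); a vector if `a`
#'   is scalar.
#' @export
ordinal_probabilities <- function(a, b, L, strict = TRUE) {
  stopifnot(length(b) == L - 1L)
  if (is.unsorted(rev(b))) {  # b must be non-increasing
    msg <- "cut points b must be non-increasing for valid probabilities"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  surv <- sigmoid(outer(a, b, `+`))             # n x (L-1), P(y > l)
  P <- cbind(1 - surv[, 1L, drop = FALSE],
             if (L > 2L) surv[, -(L - 1L), drop = FALSE] - surv[, -1L, drop = FALSE],
             surv[, L - 1L, drop = FALSE])
  colnames(P) <- NULL
  if (length(a) == 1L) drop(P) else P
}

# --- Coordinate rescaling ---------------------------------------------------

#' Fit / apply / invert the per-axis [0, 1] coordinate scaler
#'
#' Coordinates are affinely mapped to the unit square using the training
#' sections' per-axis min/max, so that losses and errors are comparable
#' across datasets and the sigmoid output head can cover the tissue.
#'
#' @param coords numeric `n x 2` matrix of tissue coordinates.
#' @return `fit_coord_scaler`: a scaler (list with `min`, `max`).
#' @export
fit_coord_scaler <- function(coords) {
  coords <- as.matrix(coords)
  lo <- apply(coords, 2L, min); hi <- apply(coords, 2L, max)
  if (any(hi - lo <= 0))
    stop("degenerate coordinate range (max = min) on an axis", call. = FALSE)
  structure(list(min = lo, max = hi), class = "coord_scaler")
}

#' @rdname fit_coord_scaler
#' @param scaler a fitted scaler.
#' @return `scale_coords`: coordinates mapped into `[0, 1]^2` (on the
#'   training range); `unscale_coords`: the exact inverse map.
#' @export
scale_coords <- function(coords, scaler) {
  coords <- as.matrix(coords)
  sweep(sweep(coords, 2L, scaler$min), 2L, scaler$max - scaler$min, "/")
}

#' @rdname fit_coord_scaler
#' @export
unscale_coords <- function(coords, scaler) {
  coords <- as.matrix(coords)
  sweep(sweep(coords, 2L, scaler$max - scaler$min, "*"), 2L, scaler$min, "+")
}
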