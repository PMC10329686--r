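# Evaluation statistics. All functions here are pure: no hidden state, and
# the only seeded path (pairwise-distance subsampling above 20k points) takes
# its seed as an explicit argument and reports the subsample in a message.

#' Top-k accuracy over ordered layers
#'
#' `k = 1`: fraction of units predicted to their true layer. `k = 2`:
#' fraction predicted to the true layer or an adjacent one under the
#' declared total order (e.g. `L1 < ... < L6 < WM`, with WM adjacent to L6).
#'
#' @param pred_labels,true_labels character/factor labels.
#' @param layer_order character vector declaring the total order.
#' @param k 1 or 2.
#' @return Fraction in `[0, 1]`.
#' @export
topk_layer_accuracy <- function(pred_labels, true_labels, layer_order, k = 1L) {
  stopifnot(k %in% c(1L, 2L), length(pred_labels) == length(true_labels))
  pi <- match(as.character(pred_labels), layer_order)
  ti <- match(as.character(true_labels), layer_order)
  if (anyNA(pi) || anyNA(ti))
    stop("labels outside the declared layer_order", call. = FALSE)
  mean(abs(pi - ti) <= (k - 1L))
}

#' Pearson correlation of true vs predicted pairwise distances
#'
#' Euclidean distances over all `C(n, 2)` unordered point pairs; invariant
#' under translation, rotation, reflection and uniform scaling of either
#' coordinate set. Above `max_points` points (default 20000), both sets are
#' restricted to one seeded subsample (logged via a message) to bound the
#' `O(n^2)` pair matrix.
#'
#' @param pred_coords,true_coords numeric `n x 2` matrices, `n >= 3`.
#' @param max_points subsampling threshold.
#' @param subsample_seed seed used only when subsampling triggers.
#' @return Pearson r in `[-1, 1]`.
#' @export
pairwise_distance_correlation <- function(pred_coords, true_coords,
                                          max_points = 20000L,
                                          subsample_seed = 1L) {
  pred_coords <- as.matrix(pred_coords); true_coords <- as.matrix(true_coords)
  n <- nrow(true_coords)
  stopifnot(n == nrow(pred_coords), n >= 3L)
  if (n > max_points) {
    set.seed(subsample_seed)
    idx <- sort(sample.int(n, max_points))
    message("pairwise_distance_correlation: subsampled ", max_points, " of ",
            n, " points (seed ", subsample_seed, ")")
    pred_coords <- pred_coords[idx, , drop = FALSE]
    true_coords <- true_coords[idx, , drop = FALSE]
  }
  dp <- as.vector(dist(pred_coords))
  dt <- as.vector(dist(true_coords))
  if (var(dp) == 0 || var(dt) == 0)
    stop("zero variance in a pairwise-distance vector; correlation undefined",
         call. = FALSE)
  cor(dp, dt)
}

#' Per-cell Euclidean localization errors
#'
#' @param pred_coords,true_coords numeric `n x 2` matrices in the SAME
#'   coordinate frame (scaled or tissue units — do not mix).
#' @return List with `errors` (per-cell distances), `median`, `q1`, `q3`,
#'   `n`.
#' @export
euclidean_errors <- function(pred_coords, true_coords) {
  pred_coords <- as.matrix(pred_coords); true_coords <- as.matrix(true_coords)
  if (!identical(dim(pred_coords), dim(true_coords)))
    stop("coordinate sets differ in shape; check the frames match",
         call. = FALSE)
  e <- sqrt(rowSums((pred_coords - true_coords)^2))
  qs <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
  list(errors = e, median = qs[2L], q1 = qs[1L], q3 = qs[3L], n = length(e))
}

#' Bin predicted cells into a grid and average a gene's expression
#'
#' Reconstructs the 2D expression map implied by predicted coordinates:
#' cells are binned into a `grid_shape[1] x grid_shape[2]` raster over the
#' unit square and each bin holds the mean expression of its cells; empty
#' bins are `NA`. Bin counts are attached as attribute `"counts"`.
#'
#' @param coords numeric `n x 2` in `[0, 1]^2`.
#' @param gene_values numeric vector, one value per cell.
#' @param grid_shape integer 2-vector, each entry `>= 2`.
#' @return Matrix of bin means (`NA` where empty).
#' @export
recovered_expression_map <- function(coords, gene_values, grid_shape) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(gene_values))
  if (any(grid_shape < 2L))
    stop("grid_shape must be at least 2 x 2", call. = FALSE)
  b1 <- pmin(pmax(ceiling(coords[, 1L] * grid_shape[1L]), 1L), grid_shape[1L])
  b2 <- pmin(pmax(ceiling(coords[, 2L] * grid_shape[2L]), 1L), grid_shape[2L])
  sums <- matrix(0, grid_shape[1L], grid_shape[2L])
  cnts <- matrix(0L, grid_shape[1L], grid_shape[2L])
  for (i in seq_along(gene_values)) {
    sums[b1[i], b2[i]] <- sums[b1[i], b2[i]] + gene_values[i]
    cnts[b1[i], b2[i]] <- cnts[b1[i], b2[i]] + 1L
  }
  out <- sums / cnts
  out[cnts == 0L] <- NA_real_
  attr(out, "counts") <- cnts
  out
}

# box-filter sums over valid entries via integral images
.box_sums <- function(m, half) {
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, n1 + 1L, n2 + 1L)
  pad[-1L, -1L] <- cs
  r1 <- pmax(seq_len(n1) - half, 1L); r2 <- pmin(seq_len(n1) + half, n1)
  c1 <- pmax(seq_len(n2) - half, 1L); c2 <- pmin(seq_len(n2) + half, n2)
  pad[r2 + 1L, c2 + 1L] - pad[r1, c2 + 1L] - pad[r2 + 1L, c1] + pad[r1, c1]
}

#' Structural similarity index between two expression maps
#'
#' Mean local SSIM with uniform square windows. Local means, variances
#' (population form, denominator N) and covariance are computed per window;
#' the stabilizers are `C1 = (K1 * range)^2`, `C2 = (K2 * range)^2` with
#' `K1 = 0.01`, `K2 = 0.03` and `range` the observed min-to-max span over
#' both images unless given. Positions missing (`NA`) in either image are
#' excluded pairwise from every window; windows with no valid pixel are
#' skipped. Identical images score exactly 1.
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @param window odd window side (default 7).
#' @param K1,K2 stabilizer constants.
#' @param dynamic_range optional positive scalar overriding the observed
#'   range.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(image_a, image_b, window = 7L, K1 = 0.01, K2 = 0.03,
                 dynamic_range = NULL) {
  if (!identical(dim(image_a), dim(image_b)))
    stop("images must have identical shape", call. = FALSE)
  valid <- !is.na(image_a) & !is.na(image_b)
  a <- ifelse(valid, image_a, 0)
  b <- ifelse(valid, image_b, 0)
  rng <- dynamic_range %||%
    max(diff(range(c(a[valid], b[valid]))), .Machine$double.eps)
  C1 <- (K1 * rng)^2; C2 <- (K2 * rng)^2
  half <- (window - 1L) %/% 2L
  nv <- .box_sums(valid * 1, half)
  ok <- nv > 0
  nvs <- ifelse(ok, nv, 1)
  ma <- .box_sums(a, half) / nvs
  mb <- .box_sums(b, half) / nvs
  va <- .box_sums(a * a, half) / nvs - ma^2
  vb <- .box_sums(b * b, half) / nvs - mb^2
  cab <- .box_sums(a * b, half) / nvs - ma * mb
  smap <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
          ((ma^2 + mb^2 + C1) * (va + vb + C2))
  mean(smap[ok])
}
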