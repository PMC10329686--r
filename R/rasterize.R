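# Step 1 of the augmentation stage: treat each gene as an image. A gene's
# 1D expression vector over spots is rearranged into an n1 x n2 matrix by
# the spots' grid indices; grid positions without a spot are coded 0 and
# excluded from the occupancy set S.

#' Rasterize per-gene expression onto the spot grid
#'
#' @param spots a normalized `SpotExpression` with `array_coords`.
#' @return A `GeneImageStack`: `images` (array `p x n1 x n2`), `mask`
#'   (`n1 x n2` logical occupancy), `coord_index` (data.frame mapping each
#'   spot to its 1-based image row/col), `S` (integer matrix of occupied
#'   positions), `gene_ids`.
#' @export
rasterize_genes <- function(spots) {
  stopifnot(is_spot(spots))
  if (is.null(spots$array_coords))
    stop("rasterize_genes() needs grid array_coords; this platform has none",
         call. = FALSE)
  r <- spots$array_coords[, 1L] - min(spots$array_coords[, 1L]) + 1L
  c <- spots$array_coords[, 2L] - min(spots$array_coords[, 2L]) + 1L
  if (anyDuplicated(cbind(r, c)))
    stop("duplicate grid positions across spots; rasterization is ambiguous",
         call. = FALSE)
  n1 <- max(r); n2 <- max(c)
  p <- length(spots$gene_ids)
  images <- array(0, dim = c(p, n1, n2))
  lin <- (c - 1L) * n1 + r  # column-major position within one image plane
  # images[j, , ] laid out with j fastest: plane offset for (r,c) is (lin-1)*p
  for (j in seq_len(p)) images[j + (lin - 1L) * p] <- spots$matrix[, j]
  mask <- matrix(FALSE, n1, n2)
  mask[lin] <- TRUE
  structure(list(images = images, mask = mask,
                 coord_index = data.frame(spot = spots$spot_ids, row = r, col = c,
                                          stringsAsFactors = FALSE),
                 S = cbind(row = r, col = c),
                 gene_ids = spots$gene_ids, n1 = n1, n2 = n2),
            class = "GeneImageStack")
}

#' @export
print.GeneImageStack <- function(x, ...) {
  cat(sprintf("GeneImageStack: %d genes on a %d x %d grid, %d occupied spots\n",
              length(x$gene_ids), x$n1, x$n2, nrow(x$S)))
  invisible(x)
}

#' Read occupied grid positions back into a spots-by-genes matrix
#'
#' Exact inverse of [rasterize_genes()] on the occupied positions; values at
#' unoccupied (hole/padding) positions are discarded.
#'
#' @param stack a `GeneImageStack`.
#' @param images optional replacement image array of the same shape (used to
#'   de-rasterize decoder output); defaults to `stack$images`.
#' @return Numeric matrix `n_spots x p` in the stack's spot and gene order.
#' @export
derasterize <- function(stack, images = stack$images) {
  stopifnot(inherits(stack, "GeneImageStack"))
  d <- dim(images)
  if (!identical(d, dim(stack$images)))
    stop("image array shape does not match the stack", call. = FALSE)
  p <- d[1L]
  lin <- (stack$coord_index$col - 1L) * stack$n1 + stack$coord_index$row
  out <- matrix(0, nrow(stack$S), p)
  for (j in seq_len(p)) out[, j] <- images[j + (lin - 1L) * p]
  dimnames(out) <- list(stack$coord_index$spot, stack$gene_ids)
  out
}

#' Cluster genes by spatial expression pattern
#'
#' Step 2 of the augmentation stage: K-means over the flattened gene images,
#' using occupied grid positions only, so genes sharing a spatial pattern
#' land in the same cluster. Cluster identity conditions the VAE decoder
#' through a one-hot vector.
#'
#' @param stack a `GeneImageStack`.
#' @param K number of clusters (default 20), `1 <= K <= p`.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return A `GeneClusterAssignment`: `cluster_of` (named integer vector in
#'   `0..K-1`), `K`, `one_hot` (`p x K` binary matrix).
#' @export
cluster_genes <- function(stack, K = 20L, seed = 1L) {
  stopifnot(inherits(stack, "GeneImageStack"))
  p <- length(stack$gene_ids)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > p) stop("K (", K, ") exceeds the number of genes (", p, ")", call. = FALSE)
  feats <- derasterize(stack)            # n_spots x p
  feats <- t(feats)                      # genes as rows
  cl <- if (K == 1L) {
    rep(1L, p)
  } else if (K == p) {
    seq_len(p)                           # one gene per cluster, deterministic
  } else {
    set.seed(seed)
    kmeans(feats, centers = K, nstart = 10L, iter.max = 100L)$cluster
  }
  one_hot <- matrix(0L, p, K)
  one_hot[cbind(seq_len(p), cl)] <- 1L
  structure(list(cluster_of = stats::setNames(cl - 1L, stack$gene_ids),
                 K = K, one_hot = one_hot),
            class = "GeneClusterAssignment")
}

#' @export
print.GeneClusterAssignment <- function(x, ...) {
  cat(sprintf("GeneClusterAssignment: %d genes in %d clusters\n",
              length(x$cluster_of), x$K))
  invisible(x)
}
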