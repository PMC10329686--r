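#' Apply a trained location model to query cells
#'
#' A pure function of `(model, query)`: repeated calls are bit-identical.
#' The query must be normalized and is matched to the model's feature gene
#' list (exact order); missing features raise an error naming the genes.
#'
#' @param object a `LocationModel`.
#' @param query a normalized `CellExpression`.
#' @param tissue_bounds bounding box of the scaled tissue used by the
#'   certainty score (ellipse task); default the unit square `c(1, 1)`
#'   side lengths.
#' @param ... unused.
#' @return A `PredictionSet` with task-appropriate fields: `coords` (scaled
#'   to `[0,1]^2`) and `coords_tissue` (original units) for `coord2d`;
#'   `ellipses` (`c1, c2, r1, r2`) plus `certainty` for `ellipse`; `probs`,
#'   `assigned`, `max_prob` for `domain`/`ordinal`. `qc_zero_features`
#'   flags cells whose whole feature vector is zero (predicted anyway).
#' @export
predict.LocationModel <- function(object, query, tissue_bounds = c(1, 1), ...) {
  stopifnot(is_cell(query))
  if (!query$normalized)
    stop("query must be normalized before prediction", call. = FALSE)
  miss <- setdiff(object$feature_genes, query$gene_ids)
  if (length(miss))
    stop("query lacks model feature genes: ",
         paste(head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) ", ..." else "", call. = FALSE)
  X <- query$matrix[, match(object$feature_genes, query$gene_ids), drop = FALSE]
  qc_zero <- rowSums(X != 0) == 0L
  out <- mlp_forward(object$params, X)$out
  res <- list(cell_ids = query$cell_ids, task = object$task,
              qc_zero_features = qc_zero)
  if (object$task == "coord2d") {
    co <- sigmoid(out)
    colnames(co) <- c("y1", "y2")
    res$coords <- co
    res$coords_tissue <- unscale_coords(co, object$scaler)
  } else if (object$task == "ellipse") {
    ell <- cbind(c1 = sigmoid(out[, 1L]), c2 = sigmoid(out[, 2L]),
                 r1 = softplus(out[, 3L]) + 1e-6,
                 r2 = softplus(out[, 4L]) + 1e-6)
    res$ellipses <- ell
    res$certainty <- certainty_score(ell, tissue_bounds)
  } else if (object$task == "domain") {
    sp <- sigmoid(out)
    probs <- sp / rowSums(sp)          # per-class sigmoids renormalized
    colnames(probs) <- object$label_set
    res$probs <- probs
  } else {
    b <- .theta_to_b(object$theta)
    probs <- ordinal_probabilities(drop(out), b, object$n_classes)
    probs <- rbind(probs)  # keep matrix shape for n = 1
    colnames(probs) <- object$label_set
    res$probs <- probs
  }
  if (!is.null(res$probs)) {
    al <- t(apply(res$probs, 1L, function(pr) assign_label(pr)))
    res$assigned <- object$label_set[as.integer(al[, 1L])]
    res$max_prob <- as.numeric(al[, 2L])
  }
  structure(res, class = "PredictionSet")
}

#' @export
print.PredictionSet <- function(x, ...) {
  cat(sprintf("PredictionSet (%s): %d cells\n", x$task, length(x$cell_ids)))
  if (!is.null(x$assigned))
    cat("  assigned labels: ",
        paste(utils::head(names(sort(table(x$assigned), decreasing = TRUE)), 3L),
              collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Certainty score of an elliptical prediction region
#'
#' `1 - min(1, pi * r1 * r2 / area(tissue bounding box))`: a cell whose
#' prediction ellipse is tiny relative to the tissue gets certainty near 1;
#' an ellipse as large as the tissue gets 0. Monotone non-increasing in
#' either semi-axis.
#'
#' @param ellipse numeric vector `(c1, c2, r1, r2)` or an `n x 4` matrix.
#' @param tissue_bounds side lengths of the tissue bounding box in scaled
#'   units (default the unit square).
#' @return Scalar or vector in `[0, 1]`.
#' @export
certainty_score <- function(ellipse, tissue_bounds = c(1, 1)) {
  area <- prod(tissue_bounds)
  if (area <= 0) stop("tissue bounding box has zero area", call. = FALSE)
  ellipse <- rbind(ellipse)
  if (any(ellipse[, 3:4] < 0))
    stop("ellipse semi-axes must be non-negative", call. = FALSE)
  out <- 1 - pmin(1, pi * ellipse[, 3L] * ellipse[, 4L] / area)
  if (nrow(ellipse) == 1L) out[[1L]] else out
}

#' Hard label assignment from a probability vector
#'
#' Argmax with ties broken toward the lowest class index.
#'
#' @param probs a probability vector (sums to 1 within 1e-6).
#' @return Numeric vector `c(label_index, max_prob)`.
#' @export
assign_label <- function(probs) {
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop("probs is not a normalized probability vector", call. = FALSE)
  i <- which.max(probs)   # which.max takes the first maximum: lowest index
  c(label = i, max_prob = probs[[i]])
}
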