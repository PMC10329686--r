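#' Spot-level expression container
#'
#' Holds an ST reference: an `n_spots x n_genes` matrix together with the
#' per-spot grid indices (`array_coords`, 0-based integer row/col on the
#' capture grid), continuous tissue positions (`spatial_coords`, columns
#' `y1`, `y2`), an optional per-spot domain/layer label drawn from a
#' declared label set, and a section identifier for multi-section designs.
#'
#' @param matrix numeric matrix, spots in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param spot_ids character vector of spot identifiers (rows).
#' @param array_coords integer matrix/data.frame with columns `row`, `col`
#'   (0-based grid indices), or `NULL` for non-grid platforms.
#' @param spatial_coords numeric matrix/data.frame with columns `y1`, `y2`.
#' @param section_id character scalar or per-spot vector; default `"S1"`.
#' @param labels optional per-spot labels (character/factor). The declared
#'   label set is taken from `label_set` or the factor levels.
#' @param label_set optional character vector declaring the (ordered) label
#'   universe; defaults to the sorted unique labels.
#' @param normalized logical; `TRUE` once [normalize_expression()] has run.
#' @return An object of class `SpotExpression`.
#' @export
spot_expression <- function(matrix, gene_ids, spot_ids,
                            array_coords = NULL, spatial_coords = NULL,
                            section_id = "S1", labels = NULL,
                            label_set = NULL, normalized = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (length(gene_ids) != ncol(matrix))
    stop("gene_ids length (", length(gene_ids),
         ") does not match matrix columns (", ncol(matrix), ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique", call. = FALSE)
  if (length(spot_ids) != nrow(matrix))
    stop("spot_ids length does not match matrix rows", call. = FALSE)
  if (length(section_id) == 1L) section_id <- rep(section_id, nrow(matrix))
  if (!is.null(array_coords)) {
    array_coords <- as.matrix(as.data.frame(array_coords)[, c("row", "col")])
    storage.mode(array_coords) <- "integer"
    dimnames(array_coords) <- list(NULL, c("row", "col"))
    key <- paste(section_id, array_coords[, 1L], array_coords[, 2L])
    if (anyDuplicated(key))
      stop("duplicate (section_id, array_coords) pairs", call. = FALSE)
  }
  if (!is.null(spatial_coords)) {
    spatial_coords <- as.matrix(as.data.frame(spatial_coords)[, c("y1", "y2")])
    storage.mode(spatial_coords) <- "double"
    dimnames(spatial_coords) <- list(NULL, c("y1", "y2"))
  }
  if (!is.null(labels)) {
    if (is.null(label_set))
      label_set <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
    labels <- as.character(labels)
    if (!all(labels %in% label_set))
      stop("labels outside the declared label set: ",
           paste(setdiff(unique(labels), label_set), collapse = ", "), call. = FALSE)
  }
  if (isTRUE(normalized) && any(!is.finite(matrix)))
    stop("normalized matrix contains non-finite entries", call. = FALSE)
  dimnames(matrix) <- list(spot_ids, gene_ids)
  structure(list(matrix = matrix, gene_ids = as.character(gene_ids),
                 spot_ids = as.character(spot_ids),
                 array_coords = array_coords, spatial_coords = spatial_coords,
                 section_id = as.character(section_id), labels = labels,
                 label_set = label_set, normalized = isTRUE(normalized),
                 gene_stats = NULL),
            class = "SpotExpression")
}

#' Cell-level expression container for the dissociated query
#'
#' @param matrix numeric matrix, cells in rows, genes in columns.
#' @param gene_ids,cell_ids identifiers (genes unique).
#' @param true_coords,true_labels optional ground truth carried by synthetic
#'   queries for validation only; never used by prediction.
#' @param normalized logical, see [normalize_expression()].
#' @return An object of class `CellExpression`.
#' @export
cell_expression <- function(matrix, gene_ids, cell_ids,
                            true_coords = NULL, true_labels = NULL,
                            normalized = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (length(gene_ids) != ncol(matrix))
    stop("gene_ids length does not match matrix columns", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (length(cell_ids) != nrow(matrix))
    stop("cell_ids length does not match matrix rows", call. = FALSE)
  if (!is.null(true_coords)) {
    true_coords <- as.matrix(as.data.frame(true_coords)[, c("y1", "y2")])
    storage.mode(true_coords) <- "double"
    dimnames(true_coords) <- list(NULL, c("y1", "y2"))
  }
  if (isTRUE(normalized) && any(!is.finite(matrix)))
    stop("normalized matrix contains non-finite entries", call. = FALSE)
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(list(matrix = matrix, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 true_coords = true_coords,
                 true_labels = if (is.null(true_labels)) NULL else as.character(true_labels),
                 normalized = isTRUE(normalized), gene_stats = NULL),
            class = "CellExpression")
}

#' @export
print.SpotExpression <- function(x, ...) {
  cat(sprintf("SpotExpression: %d spots x %d genes (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) "normalized" else "raw counts"))
  cat(sprintf("  sections: %s\n", paste(unique(x$section_id), collapse = ", ")))
  if (!is.null(x$array_coords)) cat("  grid layout: yes\n")
  if (!is.null(x$labels))
    cat(sprintf("  labels: %s\n", paste(x$label_set, collapse = " < ")))
  invisible(x)
}

#' @export
print.CellExpression <- function(x, ...) {
  cat(sprintf("CellExpression: %d cells x %d genes (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) "normalized" else "raw counts"))
  if (!is.null(x$true_coords)) cat("  carries ground-truth coordinates (synthetic)\n")
  invisible(x)
}

is_spot <- function(x) inherits(x, "SpotExpression")
is_cell <- function(x) inherits(x, "CellExpression")

#' Number of rows (spots or cells) of an expression container
#' @param x a `SpotExpression` or `CellExpression`.
#' @return integer count.
#' @export
n_units <- function(x) nrow(x$matrix)
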