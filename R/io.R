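# Readers/writers for the two plain-text dialects:
#   csv  — one table, id column + optional coordinate/label columns + genes
#   mtx  — a directory holding matrix.mtx (spots/cells x genes), genes.tsv,
#          barcodes.tsv and, for spot data, coords.tsv with the coordinate
#          columns. Matrix Market parsing is delegated to Matrix::readMM.

.COORD_COLS <- c(array = "row", array2 = "col", spatial = "y1", spatial2 = "y2")
.META_COLS <- c("row", "col", "y1", "y2", "layer", "section",
                "true_y1", "true_y2", "true_label")

#' Load an expression table from disk
#'
#' @param path file (csv) or directory (mtx) to read.
#' @param format `"csv"` or `"mtx"`.
#' @param type `"spot"` for ST references (coordinates required) or `"cell"`
#'   for dissociated queries.
#' @return A [spot_expression()] or [cell_expression()] object with raw
#'   counts preserved and `normalized = FALSE`.
#' @details The CSV dialect: first column is the spot/cell id; recognized
#' metadata columns are `row`, `col` (0-based grid indices), `y1`, `y2`
#' (tissue coordinates), `layer`, `section`, and for synthetic queries
#' `true_y1`, `true_y2`, `true_label`; every remaining column is a gene.
#' @export
load_expression <- function(path, format = c("csv", "mtx"),
                            type = c("spot", "cell")) {
  format <- match.arg(format)
  type <- match.arg(type)
  if (format == "csv") .load_csv(path, type) else .load_mtx(path, type)
}

.require_cols <- function(have, need, where) {
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing coordinate column(s) in ", where, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
}

.load_csv <- function(path, type) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  gene_cols <- setdiff(names(df), .META_COLS)
  if (!length(gene_cols)) stop("no gene columns found in ", path, call. = FALSE)
  m <- as.matrix(df[, gene_cols, drop = FALSE])
  if (type == "spot") {
    .require_cols(names(df), c("y1", "y2"), path)   # grid indices optional
    has_grid <- all(c("row", "col") %in% names(df))
    spot_expression(m, gene_ids = gene_cols, spot_ids = ids,
                    array_coords = if (has_grid) df[, c("row", "col")] else NULL,
                    spatial_coords = df[, c("y1", "y2")],
                    section_id = if ("section" %in% names(df)) df$section else "S1",
                    labels = if ("layer" %in% names(df)) df$layer else NULL)
  } else {
    cell_expression(m, gene_ids = gene_cols, cell_ids = ids,
                    true_coords = if (all(c("true_y1", "true_y2") %in% names(df)))
                      data.frame(y1 = df$true_y1, y2 = df$true_y2) else NULL,
                    true_labels = if ("true_label" %in% names(df)) df$true_label else NULL)
  }
}

.load_mtx <- function(dir, type) {
  mm <- file.path(dir, "matrix.mtx")
  if (!file.exists(mm)) stop("no matrix.mtx under ", dir, call. = FALSE)
  m <- as.matrix(Matrix::readMM(mm))
  genes <- readLines(file.path(dir, "genes.tsv"))
  ids <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != ncol(m))
    stop("gene-count mismatch: genes.tsv has ", length(genes),
         " entries but matrix has ", ncol(m), " columns", call. = FALSE)
  if (type == "cell")
    return(cell_expression(m, gene_ids = genes, cell_ids = ids))
  cf <- file.path(dir, "coords.tsv")
  if (!file.exists(cf))
    stop("missing coordinate column(s) in ", dir,
         ": no coords.tsv (need row, col, y1, y2)", call. = FALSE)
  co <- read.delim(cf, stringsAsFactors = FALSE)
  .require_cols(names(co), c("y1", "y2"), cf)
  co <- co[match(ids, co[[1L]]), , drop = FALSE]
  has_grid <- all(c("row", "col") %in% names(co))
  spot_expression(m, gene_ids = genes, spot_ids = ids,
                  array_coords = if (has_grid) co[, c("row", "col")] else NULL,
                  spatial_coords = co[, c("y1", "y2")],
                  section_id = if ("section" %in% names(co)) co$section else "S1",
                  labels = if ("layer" %in% names(co)) co$layer else NULL)
}

#' Write an expression container to a CSV table
#'
#' Integer counts round-trip losslessly through [load_expression()];
#' coordinates are written at full precision.
#'
#' @param x a `SpotExpression` or `CellExpression`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
save_expression <- function(x, path) {
  m <- x$matrix
  if (!x$normalized && all(m == round(m))) storage.mode(m) <- "integer"
  if (is_spot(x)) {
    df <- data.frame(spot_id = x$spot_ids, stringsAsFactors = FALSE)
    if (!is.null(x$array_coords)) { df$row <- x$array_coords[, 1L]; df$col <- x$array_coords[, 2L] }
    if (!is.null(x$spatial_coords)) { df$y1 <- x$spatial_coords[, 1L]; df$y2 <- x$spatial_coords[, 2L] }
    if (!is.null(x$labels)) df$layer <- x$labels
    df$section <- x$section_id
  } else {
    df <- data.frame(cell_id = x$cell_ids, stringsAsFactors = FALSE)
    if (!is.null(x$true_coords)) { df$true_y1 <- x$true_coords[, 1L]; df$true_y2 <- x$true_coords[, 2L] }
    if (!is.null(x$true_labels)) df$true_label <- x$true_labels
  }
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
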