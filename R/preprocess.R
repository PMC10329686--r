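#' Normalize UMI counts: log1p then per-gene standardization
#'
#' Two-step normalization: (1) spot/cell-level `log(1 + count)` transform of
#' the UMI counts; (2) gene-level z-score — subtract each gene's mean across
#' all spots/cells and divide by its standard deviation. Genes with zero
#' variance after the log transform have an undefined z-score and are
#' dropped with a warning. The per-gene mean/SD on the log1p scale are kept
#' in `$gene_stats` so that downstream variance-based gene ranking can see
#' dispersion that the z-score erases.
#'
#' @param x a raw-count `SpotExpression` or `CellExpression`.
#' @return The same class of object with `normalized = TRUE`.
#' @export
normalize_expression <- function(x) {
  stopifnot(is_spot(x) || is_cell(x))
  if (x$normalized)
    stop("data are already normalized; normalize_expression() must run once",
         call. = FALSE)
  if (any(x$matrix < 0))
    stop("negative counts encountered; expected raw UMI counts", call. = FALSE)
  lg <- log1p(x$matrix)
  mu <- colMeans(lg)
  sdev <- apply(lg, 2L, sd)
  keep <- sdev > 0
  if (!any(keep))
    stop("all genes have zero variance; nothing to normalize", call. = FALSE)
  if (any(!keep))
    warning(sum(!keep), " zero-variance gene(s) dropped: ",
            paste(head(x$gene_ids[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "", call. = FALSE)
  z <- sweep(sweep(lg[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdev[keep], "/")
  x$matrix <- z
  x$gene_ids <- x$gene_ids[keep]
  x$normalized <- TRUE
  x$gene_stats <- data.frame(gene = x$gene_ids, mean_log1p = mu[keep],
                             sd_log1p = sdev[keep], row.names = NULL)
  x
}

#' Rank and select informative genes from a normalized reference
#'
#' `mode = "variance"` ranks genes by their cross-spot variance on the
#' log1p scale (recorded at normalization time; after z-scoring every gene
#' has unit variance, so ranking must use the pre-standardization scale).
#' `mode = "label_markers"` ranks genes per label by a Wilcoxon rank-sum
#' test of that label's spots against all others and pools the top-ranked
#' genes across labels round-robin, which spreads the budget evenly over
#' domains — an internal stand-in for external spatially-variable-gene or
#' DE-gene selection tools.
#'
#' @param reference a normalized `SpotExpression`.
#' @param n_top maximum number of genes to return.
#' @param mode `"variance"` or `"label_markers"`.
#' @return Character vector of at most `n_top` gene ids, ranked.
#' @export
select_genes <- function(reference, n_top,
                         mode = c("variance", "label_markers")) {
  mode <- match.arg(mode)
  stopifnot(is_spot(reference))
  if (!reference$normalized)
    stop("reference must be normalized first", call. = FALSE)
  p <- length(reference$gene_ids)
  if (mode == "variance") {
    v <- reference$gene_stats$sd_log1p^2
    ord <- order(-v, reference$gene_ids)  # variance desc, id asc for ties
    return(reference$gene_ids[ord][seq_len(min(n_top, p))])
  }
  if (is.null(reference$labels))
    stop("mode = 'label_markers' requires per-spot labels", call. = FALSE)
  labs <- reference$labels
  ranked <- lapply(unique(labs), function(lab) {
    inl <- labs == lab
    stat <- vapply(seq_len(p), function(j) {
      # large |z|-like statistic first: use Wilcoxon p-value ascending
      suppressWarnings(wilcox.test(reference$matrix[inl, j],
                                   reference$matrix[!inl, j],
                                   exact = FALSE)$p.value)
    }, numeric(1))
    reference$gene_ids[order(stat, reference$gene_ids)]
  })
  out <- character(0)
  i <- 1L
  while (length(out) < min(n_top, p)) {  # round-robin across labels
    for (r in ranked) {
      if (i <= length(r) && !(r[i] %in% out)) out <- c(out, r[i])
      if (length(out) >= min(n_top, p)) break
    }
    i <- i + 1L
  }
  out
}

#' Merge multiple ST sections into one training reference
#'
#' Each section is normalized independently (sections given raw are
#' normalized here, one by one), the gene set is restricted to the exact
#' intersection across sections, and rows are concatenated with their
#' section ids retained.
#'
#' @param sections list of `SpotExpression` objects.
#' @return A single normalized `SpotExpression`.
#' @export
merge_sections <- function(sections) {
  stopifnot(length(sections) >= 1L, all(vapply(sections, is_spot, logical(1))))
  sections <- lapply(sections, function(s)
    if (s$normalized) s else normalize_expression(s))
  common <- Reduce(intersect, lapply(sections, `[[`, "gene_ids"))
  if (!length(common))
    stop("empty gene intersection across sections", call. = FALSE)
  common <- sort(common)
  parts <- lapply(sections, function(s)
    s$matrix[, match(common, s$gene_ids), drop = FALSE])
  lab_all <- if (all(!vapply(sections, function(s) is.null(s$labels), logical(1))))
    unlist(lapply(sections, `[[`, "labels")) else NULL
  lset <- if (!is.null(lab_all))
    Reduce(union, lapply(sections, `[[`, "label_set")) else NULL
  out <- spot_expression(
    do.call(rbind, parts), gene_ids = common,
    spot_ids = make.unique(unlist(lapply(sections, `[[`, "spot_ids"))),
    array_coords = if (all(!vapply(sections, function(s) is.null(s$array_coords), logical(1))))
      do.call(rbind, lapply(sections, `[[`, "array_coords")) else NULL,
    spatial_coords = if (all(!vapply(sections, function(s) is.null(s$spatial_coords), logical(1))))
      do.call(rbind, lapply(sections, `[[`, "spatial_coords")) else NULL,
    section_id = unlist(lapply(sections, `[[`, "section_id")),
    labels = lab_all, label_set = lset, normalized = TRUE)
  out$gene_stats <- NULL  # per-section scales differ; variance ranking n/a
  out
}

#' Restrict reference and query to a shared, identically ordered gene set
#'
#' The trained model's feature vector must match the query column-for-column;
#' both objects are cut down to the gene intersection in lexicographic order.
#'
#' @param reference a `SpotExpression`.
#' @param query a `CellExpression`.
#' @return A list with elements `reference` and `query`.
#' @export
harmonize_genes <- function(reference, query) {
  common <- sort(intersect(reference$gene_ids, query$gene_ids))
  if (!length(common))
    stop("reference and query share no genes", call. = FALSE)
  .subset_genes <- function(x, genes) {
    idx <- match(genes, x$gene_ids)
    x$matrix <- x$matrix[, idx, drop = FALSE]
    x$gene_ids <- genes
    if (!is.null(x$gene_stats)) x$gene_stats <- x$gene_stats[idx, , drop = FALSE]
    x
  }
  list(reference = .subset_genes(reference, common),
       query = .subset_genes(query, common))
}

#' Keep genes not differentially expressed between two conditions
#'
#' For applications where disease-associated expression shifts would bias
#' localization (e.g., mapping cells from affected tissue with a healthy
#' reference), genes that differ between the two condition groups are
#' removed. Per gene, a Wilcoxon rank-sum test between the groups is
#' Benjamini-Hochberg adjusted; genes with adjusted p >= `fdr` are retained.
#'
#' @param query a `CellExpression`.
#' @param condition_labels two-level factor/character vector, one per cell.
#' @param fdr adjusted-p threshold (default 0.05). `fdr = 0` retains every
#'   gene (Wilcoxon p-values are strictly positive).
#' @return Character vector of retained gene ids.
#' @export
filter_condition_invariant_genes <- function(query, condition_labels, fdr = 0.05) {
  stopifnot(is_cell(query))
  condition_labels <- as.character(condition_labels)
  lv <- unique(condition_labels)
  if (length(lv) != 2L)
    stop("condition_labels must have exactly two levels", call. = FALSE)
  g1 <- condition_labels == lv[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("need at least 2 cells per condition group", call. = FALSE)
  p <- vapply(seq_along(query$gene_ids), function(j) {
    a <- query$matrix[g1, j]; b <- query$matrix[!g1, j]
    if (all(a == a[1L]) && all(b == b[1L]) && a[1L] == b[1L]) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  query$gene_ids[padj >= fdr]
}
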