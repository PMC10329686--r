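# Seeded generators for a layered rectangular tissue on a Visium-like grid:
# ordered layer bands along one axis, holes, and a gene panel mixing layer
# markers, smooth spatial gradients, radial bumps, co-expressed clusters and
# null genes. Counts are Poisson with a log-link intensity, matching the
# log1p + z-score preprocessing the method expects.

#' Gene pattern constructors for [tissue_spec()]
#'
#' Each pattern contributes to the log-intensity at normalized position
#' `(u, v)` in the unit square (`u` along the band axis):
#' * `layer_marker(layer, effect)` — adds `effect` inside one layer band;
#' * `linear_gradient(direction, slope)` — adds
#'   `slope * (cos(direction) u + sin(direction) v)` (direction in radians);
#' * `radial_bump(center, width, height)` — adds a Gaussian bump
#'   `height * exp(-d^2 / (2 width^2))` around `center` (unit-square units);
#' * `coexpressed_cluster(cluster_id)` — shares that cluster's template (a
#'   seeded bump + gradient) with every gene carrying the same id;
#' * `null_gene()` — baseline intensity only.
#'
#' @param layer 1-based layer index.
#' @param effect,slope,height log-intensity effect sizes.
#' @param direction angle in radians.
#' @param center length-2 center in the unit square.
#' @param width bump SD in unit-square units.
#' @param cluster_id integer cluster identity.
#' @return A pattern descriptor list.
#' @name gene_patterns
NULL

#' @rdname gene_patterns
#' @export
layer_marker <- function(layer, effect = 2)
  list(kind = "layer_marker", layer = as.integer(layer), effect = effect)

#' @rdname gene_patterns
#' @export
linear_gradient <- function(direction = 0, slope = 2)
  list(kind = "linear_gradient", direction = direction, slope = slope)

#' @rdname gene_patterns
#' @export
radial_bump <- function(center = c(0.5, 0.5), width = 0.2, height = 2)
  list(kind = "radial_bump", center = center, width = width, height = height)

#' @rdname gene_patterns
#' @export
coexpressed_cluster <- function(cluster_id)
  list(kind = "coexpressed_cluster", cluster_id = as.integer(cluster_id))

#' @rdname gene_patterns
#' @export
null_gene <- function() list(kind = "null")

#' Declare a synthetic layered tissue
#'
#' @param grid integer 2-vector `(n1, n2)` of grid rows/columns.
#' @param hole_fraction fraction of grid positions without a spot, in
#'   `[0, 0.5]`.
#' @param n_layers number of ordered layer bands along the band axis
#'   (rows by default); band boundaries are equally spaced.
#' @param genes list of pattern descriptors (see [gene_patterns]); names
#'   become gene ids (defaults `g001, g002, ...`).
#' @param baseline baseline log-intensity (default `log(5)`: a typical
#'   moderately expressed gene at ~5 UMI per spot).
#' @param band_axis `"row"` (default) or `"col"`.
#' @param seed integer seed owning every random draw derived from the spec
#'   (hole placement, cluster templates, counts).
#' @return A `TissueSpec`.
#' @export
tissue_spec <- function(grid = c(20L, 20L), hole_fraction = 0.1,
                        n_layers = 4L, genes = list(),
                        baseline = log(5), band_axis = c("row", "col"),
                        seed = 1L) {
  band_axis <- match.arg(band_axis)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 2L))
    stop("grid must be two dimensions of at least 2", call. = FALSE)
  if (hole_fraction < 0 || hole_fraction > 0.5)
    stop("hole_fraction must lie in [0, 0.5]", call. = FALSE)
  if (!length(genes)) stop("gene panel must not be empty", call. = FALSE)
  if (is.null(names(genes)) || any(names(genes) == ""))
    names(genes) <- sprintf("g%03d", seq_along(genes))
  structure(list(grid = grid, hole_fraction = hole_fraction,
                 n_layers = as.integer(n_layers), genes = genes,
                 baseline = baseline, band_axis = band_axis,
                 seed = as.integer(seed)),
            class = "TissueSpec")
}

# layer index of normalized band-axis position u in [0, 1]
.layer_of <- function(u, L) pmin(pmax(ceiling(u * L), 1L), L)

# cluster templates are a deterministic function of the spec seed: a bump at
# a seeded center plus a seeded gradient, so genes sharing a cluster_id
# share a pattern distinct from other clusters'
.cluster_templates <- function(spec) {
  ids <- unique(vapply(spec$genes, function(g)
    if (g$kind == "coexpressed_cluster") g$cluster_id else NA_integer_,
    integer(1)))
  ids <- sort(ids[!is.na(ids)])
  if (!length(ids)) return(NULL)
  old <- .Random.seed_save()
  set.seed(spec$seed + 99991L)
  tpl <- lapply(ids, function(i)
    list(center = runif(2, 0.15, 0.85), width = runif(1, 0.12, 0.2),
         height = runif(1, 1.5, 2.5),
         direction = runif(1, 0, 2 * pi), slope = runif(1, 0.5, 1)))
  names(tpl) <- as.character(ids)
  .Random.seed_restore(old)
  tpl
}

.Random.seed_save <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
.Random.seed_restore <- function(old)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

# log-intensity of one gene at normalized positions (u = band axis, v other)
.pattern_logint <- function(g, u, v, L, templates) {
  switch(g$kind,
    layer_marker = ifelse(.layer_of(u, L) == g$layer, g$effect, 0),
    linear_gradient = g$slope * (cos(g$direction) * u + sin(g$direction) * v),
    radial_bump = g$height *
      exp(-((u - g$center[1L])^2 + (v - g$center[2L])^2) / (2 * g$width^2)),
    coexpressed_cluster = {
      t <- templates[[as.character(g$cluster_id)]]
      t$height * exp(-((u - t$center[1L])^2 + (v - t$center[2L])^2) /
                       (2 * t$width^2)) +
        t$slope * (cos(t$direction) * u + sin(t$direction) * v)
    },
    null = rep(0, length(u)),
    stop("unknown gene pattern kind: ", g$kind, call. = FALSE))
}

.logint_matrix <- function(spec, u, v) {
  templates <- .cluster_templates(spec)
  li <- vapply(spec$genes, function(g)
    spec$baseline + .pattern_logint(g, u, v, spec$n_layers, templates),
    numeric(length(u)))
  if (length(u) == 1L) li <- rbind(li)
  li
}

#' Generate a synthetic ST reference from a tissue spec
#'
#' Spots occupy the non-hole grid positions; per-spot per-gene counts are
#' `Poisson(exp(log-intensity))`; true layer labels (`band1 < band2 < ...`)
#' are attached. Deterministic given the spec's seed.
#'
#' @param spec a [tissue_spec()].
#' @return A raw-count `SpotExpression` with `array_coords`,
#'   `spatial_coords` (the grid positions as tissue units) and labels.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "TissueSpec"))
  n1 <- spec$grid[1L]; n2 <- spec$grid[2L]
  set.seed(spec$seed)
  pos <- expand.grid(row = seq_len(n1) - 1L, col = seq_len(n2) - 1L)
  n_holes <- floor(spec$hole_fraction * nrow(pos))
  if (n_holes > 0L) pos <- pos[-sample.int(nrow(pos), n_holes), , drop = FALSE]
  band <- if (spec$band_axis == "row") (pos$row + 0.5) / n1 else (pos$col + 0.5) / n2
  other <- if (spec$band_axis == "row") (pos$col + 0.5) / n2 else (pos$row + 0.5) / n1
  li <- .logint_matrix(spec, band, other)
  counts <- matrix(rpois(length(li), exp(li)), nrow(pos),
                   length(spec$genes))
  layers <- paste0("band", .layer_of(band, spec$n_layers))
  spot_expression(counts, gene_ids = names(spec$genes),
                  spot_ids = sprintf("spot%05d", seq_len(nrow(pos))),
                  array_coords = pos,
                  spatial_coords = data.frame(y1 = pos$row, y2 = pos$col),
                  labels = layers,
                  label_set = paste0("band", seq_len(spec$n_layers)))
}

#' Generate a synthetic dissociated query from the same tissue model
#'
#' `m` cells at uniformly sampled continuous positions draw counts from the
#' tissue model. The query is normalized (log1p + z-score across the query
#' cells) and, emulating noisy test data, i.i.d. Gaussian noise with SD
#' `noise_sd` is added to the standardized expression. True positions
#' (in grid units, matching the reference's `spatial_coords` frame) and
#' true layer labels are stored for validation.
#'
#' @param spec a [tissue_spec()].
#' @param m number of cells.
#' @param noise_sd standard deviation of the post-normalization Gaussian
#'   noise; `>= 0`.
#' @param seed RNG seed (independent of the reference's).
#' @param normalize set `FALSE` to get raw counts (only allowed with
#'   `noise_sd = 0`, since noise is defined on the standardized scale).
#' @return A `CellExpression` with `true_coords` and `true_labels`.
#' @export
make_query <- function(spec, m, noise_sd = 0, seed = 2L, normalize = TRUE) {
  stopifnot(inherits(spec, "TissueSpec"), m >= 1L)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!normalize && noise_sd > 0)
    stop("noise is applied on the normalized scale; use normalize = TRUE",
         call. = FALSE)
  n1 <- spec$grid[1L]; n2 <- spec$grid[2L]
  set.seed(seed)
  rowpos <- runif(m, 0, n1 - 1L)   # continuous positions in grid units
  colpos <- runif(m, 0, n2 - 1L)
  band <- if (spec$band_axis == "row") (rowpos + 0.5) / n1 else (colpos + 0.5) / n2
  other <- if (spec$band_axis == "row") (colpos + 0.5) / n2 else (rowpos + 0.5) / n1
  li <- .logint_matrix(spec, band, other)
  counts <- matrix(rpois(length(li), exp(li)), m, length(spec$genes))
  q <- cell_expression(counts, gene_ids = names(spec$genes),
                       cell_ids = sprintf("cell%05d", seq_len(m)),
                       true_coords = data.frame(y1 = rowpos, y2 = colpos),
                       true_labels = paste0("band", .layer_of(band, spec$n_layers)))
  if (!normalize) return(q)
  q <- normalize_expression(q)
  if (noise_sd > 0)
    q$matrix <- q$matrix + matrix(rnorm(length(q$matrix), sd = noise_sd),
                                  nrow(q$matrix), ncol(q$matrix))
  q
}

#' Build a co-expressed gene panel fragment for augmentation tests
#'
#' `K` families of `genes_per_cluster` genes, each family sharing one
#' spatial template. Templates (Gaussian bumps on a seeded layout plus a
#' seeded gradient) must be pairwise at least `separation` apart in
#' normalized L2 distance over the grid, otherwise an error reports the
#' infeasibility.
#'
#' @param K number of clusters, `>= 2`.
#' @param genes_per_cluster genes per family.
#' @param separation minimum pairwise template distance (normalized L2 of
#'   unit-norm templates, in `[0, 2]`).
#' @param seed template seed.
#' @param grid grid used to check separation (default `c(20, 20)`).
#' @return Named list of `K * genes_per_cluster` gene patterns, usable as
#'   the `genes` argument of [tissue_spec()] (with the same `seed`).
#' @export
make_cluster_panel <- function(K, genes_per_cluster = 5L, separation = 0.5,
                               seed = 1L, grid = c(20L, 20L)) {
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  genes <- list()
  for (k in seq_len(K)) for (g in seq_len(genes_per_cluster))
    genes[[sprintf("clu%02d_g%02d", k, g)]] <- coexpressed_cluster(k)
  spec <- tissue_spec(grid = grid, hole_fraction = 0, n_layers = 2L,
                      genes = genes, seed = seed)
  tpl <- .cluster_templates(spec)
  u <- (rep(seq_len(grid[1L]), times = grid[2L]) - 0.5) / grid[1L]
  v <- (rep(seq_len(grid[2L]), each = grid[1L]) - 0.5) / grid[2L]
  fields <- vapply(names(tpl), function(id) {
    f <- .pattern_logint(coexpressed_cluster(as.integer(id)), u, v, 2L, tpl)
    f / sqrt(sum(f^2))
  }, numeric(length(u)))
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    d <- sqrt(sum((fields[, a] - fields[, b])^2))
    if (d < separation)
      stop(sprintf(paste0("cluster templates %d and %d are only %.3f apart ",
                          "(< separation %.3f); infeasible for this grid/seed"),
                   a, b, d, separation), call. = FALSE)
  }
  genes
}
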