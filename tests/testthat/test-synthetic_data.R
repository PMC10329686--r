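test_that("make_reference respects the grid, holes, seeds and band structure", {
  spec <- tissue_spec(grid = c(10, 10), hole_fraction = 0, n_layers = 4,
                      genes = gradient_panel(3, 1, seed = 1), seed = 5)
  ref <- make_reference(spec)
  expect_equal(nrow(ref$matrix), 100)           # no holes -> full grid
  expect_identical(make_reference(spec)$matrix, ref$matrix)  # seed-determinism

  spec2 <- tissue_spec(grid = c(20, 15), hole_fraction = 0.25, n_layers = 3,
                       genes = gradient_panel(3, 1, seed = 1), seed = 6)
  ref2 <- make_reference(spec2)
  expect_equal(nrow(ref2$matrix), 300 - floor(0.25 * 300))

  # labels form contiguous bands along the row axis
  for (lab in unique(ref2$labels)) {
    rows <- range(ref2$array_coords[ref2$labels == lab, "row"])
    other <- ref2$array_coords[ref2$labels != lab, "row"]
    expect_true(all(other < rows[1] | other > rows[2]))
  }

  expect_error(tissue_spec(grid = c(1, 5), genes = gradient_panel(2, 0)),
               "grid")
  expect_error(tissue_spec(hole_fraction = 0.7, genes = gradient_panel(2, 0)),
               "hole_fraction")
})

test_that("layer-marker genes are elevated inside their band", {
  genes <- list(mk = layer_marker(2, effect = 2), nl = null_gene())
  spec <- tissue_spec(grid = c(24, 24), hole_fraction = 0, n_layers = 3,
                      genes = genes, seed = 9)
  ref <- make_reference(spec)
  inside <- ref$labels == "band2"
  tt <- t.test(ref$matrix[inside, "mk"], ref$matrix[!inside, "mk"],
               alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  # null gene shows no such shift
  tn <- t.test(ref$matrix[inside, "nl"], ref$matrix[!inside, "nl"])
  expect_gt(tn$p.value, 0.01)
})

test_that("make_query matches the tissue model and applies calibrated noise", {
  spec <- tissue_spec(grid = c(16, 16), hole_fraction = 0, n_layers = 2,
                      genes = gradient_panel(6, 2, seed = 3), seed = 11)
  q0 <- make_query(spec, 500, noise_sd = 0, seed = 21)
  expect_equal(nrow(q0$matrix), 500)            # m respected exactly
  expect_true(q0$normalized)
  expect_identical(make_query(spec, 500, 0, seed = 21)$matrix, q0$matrix)

  # noiseless query raw counts are exchangeable with reference spots:
  # per-gene mean log1p counts agree (two-sample test not rejected at 0.01)
  ref <- make_reference(spec)
  qr <- make_query(spec, 1000, 0, seed = 22, normalize = FALSE)
  pv <- vapply(seq_along(ref$gene_ids), function(j)
    t.test(log1p(ref$matrix[, j]), log1p(qr$matrix[, j]))$p.value, numeric(1))
  expect_gt(min(p.adjust(pv, "bonferroni")), 0.01)

  # noise_sd = 10: per-gene SD ~ sqrt(1 + 100) of the noiseless (unit) SD
  qn <- make_query(spec, 1000, 10, seed = 23)
  sds <- apply(qn$matrix, 2, sd)
  expect_true(all(abs(sds / sqrt(101) - 1) < 0.1))

  expect_error(make_query(spec, 10, noise_sd = -1), "noise_sd")
  expect_error(make_query(spec, 10, noise_sd = 2, normalize = FALSE),
               "normalized scale")
})

test_that("make_cluster_panel emits separable families or refuses", {
  genes <- make_cluster_panel(3, 4, separation = 0.3, seed = 7, grid = c(16, 16))
  expect_length(genes, 12)                      # K * genes_per_cluster
  spec <- tissue_spec(grid = c(16, 16), hole_fraction = 0, n_layers = 2,
                      genes = genes, seed = 7)
  ref <- normalize_expression(make_reference(spec))
  # within-family image correlation exceeds across-family correlation
  fam <- rep(1:3, each = 4)
  cm <- cor(ref$matrix)
  within <- cm[outer(fam, fam, "==") & upper.tri(cm)]
  across <- cm[outer(fam, fam, "!=") & upper.tri(cm)]
  expect_gt(mean(within), mean(across))

  expect_error(make_cluster_panel(1, 4), "K must be >= 2")
  expect_error(make_cluster_panel(8, 2, separation = 1.9, seed = 1),
               "infeasible")
})
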