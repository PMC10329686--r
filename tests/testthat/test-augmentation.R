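test_that("rasterization places spots on the grid, zeros holes, and round-trips", {
  ref <- normalize_expression(tiny_spots(n1 = 10, n2 = 8, hole_fraction = 0.2,
                                         seed = 13))
  stack <- rasterize_genes(ref)
  expect_equal(sum(stack$mask), nrow(ref$matrix))
  expect_true(stack$n1 * stack$n2 >= nrow(ref$matrix))
  # unoccupied positions hold exactly 0
  for (j in seq_along(stack$gene_ids))
    expect_true(all(stack$images[j, , ][!stack$mask] == 0))
  # occupied-cell sum of image j equals the column sum of the matrix (oracle)
  for (j in seq_along(stack$gene_ids))
    expect_equal(sum(stack$images[j, , ]), sum(ref$matrix[, j]))
  # derasterize . rasterize = identity
  expect_equal(derasterize(stack), ref$matrix, ignore_attr = TRUE)

  dup <- ref
  dup$array_coords[2, ] <- dup$array_coords[1, ]
  expect_error(rasterize_genes(dup), "duplicate grid positions")
  nogrid <- ref; nogrid$array_coords <- NULL
  expect_error(rasterize_genes(nogrid), "array_coords")
})

test_that("a minimal 2x2 grid with one hole rasterizes as documented", {
  x <- spot_expression(matrix(1, 3, 1), "g", paste0("s", 1:3),
                       array_coords = data.frame(row = c(0, 0, 1),
                                                 col = c(0, 1, 0)),
                       normalized = TRUE)
  st <- rasterize_genes(x)
  expect_equal(sum(st$mask), 3)
  expect_equal(sum(st$images[1, , ] == 1), 3)
  expect_equal(sum(st$images[1, , ] == 0), 1)
})

test_that("gene clustering recovers planted pattern families and honors edge cases", {
  genes <- make_cluster_panel(2, 8, separation = 0.3, seed = 5, grid = c(16, 16))
  spec <- tissue_spec(grid = c(16, 16), hole_fraction = 0.1, n_layers = 2,
                      genes = genes, seed = 5)
  ref <- normalize_expression(make_reference(spec))
  stack <- rasterize_genes(ref)
  truth <- rep(1:2, each = 8)

  cl <- cluster_genes(stack, K = 2, seed = 1)
  expect_equal(adjusted_rand_index(cl$cluster_of, truth), 1.0)
  expect_true(all(rowSums(cl$one_hot) == 1))
  expect_identical(cluster_genes(stack, K = 2, seed = 1)$cluster_of,
                   cl$cluster_of)   # deterministic given seed

  expect_equal(unname(cluster_genes(stack, K = 1)$cluster_of),
               rep(0L, 16))
  all_own <- cluster_genes(stack, K = 16)
  expect_equal(length(unique(all_own$cluster_of)), 16)
  expect_error(cluster_genes(stack, K = 17), "exceeds")
})

test_that("kl_divergence matches the closed form, the loop oracle and Monte Carlo", {
  expect_equal(kl_divergence(rep(0, 4), rep(1, 4)), 0)
  expect_equal(kl_divergence(1, 1), 0.5)
  expect_error(kl_divergence(0, 0), "positive")
  expect_error(kl_divergence(c(0, 0), 1), "length")

  set.seed(77)
  for (i in 1:5) {
    mu <- rnorm(4); sigma <- exp(rnorm(4, sd = 0.5))
    expect_equal(kl_divergence(mu, sigma), naive_kl(mu, sigma),
                 tolerance = 1e-12)
    expect_gte(kl_divergence(mu, sigma), 0)
  }
  # sampling oracle on one draw (the full 20-draw version runs in acceptance)
  mu <- rnorm(1); sigma <- exp(rnorm(1, sd = 0.5))
  mc <- mc_kl(mu, sigma, 2e5)
  expect_lt(abs(kl_divergence(mu, sigma) - mc["est"]), 3 * mc["se"])
})

test_that("augmenter_loss decomposes exactly and matches the triple-loop oracle", {
  set.seed(3)
  p <- 3; n1 <- 4; n2 <- 5; D <- 3
  X <- array(rnorm(p * n1 * n2), c(p, n1, n2))
  Xh <- X + array(rnorm(p * n1 * n2, sd = 0.3), c(p, n1, n2))
  mu <- matrix(rnorm(p * D), p, D)
  sigma <- matrix(exp(rnorm(p * D, sd = 0.3)), p, D)
  mask <- matrix(runif(n1 * n2) < 0.8, n1, n2)
  beta <- 1e-3
  got <- augmenter_loss(X, Xh, mu, sigma, beta, mask)
  want <- naive_augmenter_loss(X, Xh, mu, sigma, beta, mask)
  expect_equal(got$recon, want$recon, tolerance = 1e-12)
  expect_equal(got$kl, want$kl, tolerance = 1e-12)
  expect_equal(got$total - beta * got$kl - got$recon, 0)  # exact decomposition

  zero <- augmenter_loss(X, X, matrix(0, p, D), matrix(1, p, D), beta, mask)
  expect_equal(unlist(zero), c(total = 0, recon = 0, kl = 0))
  b0 <- augmenter_loss(X, Xh, mu, sigma, 0, mask)
  expect_identical(b0$total, b0$recon)
  expect_error(augmenter_loss(X, Xh[, 1:3, ], mu, sigma), "identical shape")
})

test_that("the VAE trains, is seed-deterministic, and replicates resemble the source", {
  genes <- make_cluster_panel(2, 6, separation = 0.3, seed = 5, grid = c(16, 16))
  spec <- tissue_spec(grid = c(16, 16), hole_fraction = 0.1, n_layers = 2,
                      genes = genes, seed = 5)
  ref <- normalize_expression(make_reference(spec))
  stack <- rasterize_genes(ref)
  cl <- cluster_genes(stack, K = 2, seed = 1)
  cfg <- augmenter_config(embedding_dim = 16, epochs = 120)
  expect_equal(cfg$beta, 1e-5)           # default KL weight
  expect_equal(augmenter_config()$embedding_dim, 512L)  # default embedding

  m <- train_augmenter(stack, cl, cfg, seed = 2)
  expect_lt(tail(m$log$total, 1), m$log$total[1])   # improved on init
  expect_true(m$converged)
  expect_equal(nrow(m$log), 120)
  expect_true(all(m$sigma > 0))

  m2 <- train_augmenter(stack, cl, cfg, seed = 2)
  expect_identical(m2$pars, m$pars)       # same seed -> identical parameters

  reps <- generate_replicates(m, stack, cl, R = 2, seed = 9)
  expect_length(reps$replicates, 2)
  for (r in reps$replicates)
    expect_identical(dim(r), dim(ref$matrix))
  # replicates differ across draws for at least one gene
  dvar <- apply(reps$replicates[[1]] - reps$replicates[[2]], 2, var)
  expect_true(any(dvar > 0))

  untrained <- m; untrained$trained <- FALSE
  expect_error(generate_replicates(untrained, stack, cl), "not a trained")
})

test_that("checkpoints round-trip models with a JSON sidecar", {
  ref <- normalize_expression(tiny_spots(seed = 2))
  model <- train_location_model(ref, config = location_model_config(
    "coord2d", hidden_sizes = c(8), epochs = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$format, "spotloc-checkpoint-v1")
  expect_equal(side$class, "LocationModel")
})
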