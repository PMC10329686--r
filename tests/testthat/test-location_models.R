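test_that("all four losses reproduce their hand-computed worked examples", {
  # coordinate loss: one spot, truth (0.2, 0.4), pred (0.5, 0.8)
  expect_equal(coord_loss(rbind(c(0.5, 0.8)), rbind(c(0.2, 0.4))), 0.25)
  expect_equal(coord_loss(rbind(c(0.2, 0.4)), rbind(c(0.2, 0.4))), 0)

  # ellipse loss: boundary, center and far-outside points at alpha = 0.9
  ell <- rbind(c(0.5, 0.5, 0.1, 0.2))
  expect_equal(ellipse_loss(ell, rbind(c(0.6, 0.5)), 0.9), 0)     # q = 1
  expect_equal(ellipse_loss(ell, rbind(c(0.5, 0.5)), 0.9), 0.1)   # q = 0
  expect_equal(ellipse_loss(ell, rbind(c(0.7, 0.5)), 0.9), 2.7)   # q = 4
  expect_error(ellipse_loss(rbind(c(0.5, 0.5, 0, 0.1)),
                            rbind(c(0.5, 0.5)), 0.9), "positive")

  # domain loss: C = 2, zero scores, one sample -> 2 log 2
  expect_equal(domain_loss(rbind(c(0, 0)), 1, 2), 2 * log(2))
  # perfectly confident scores drive the loss to ~0
  expect_lt(domain_loss(rbind(c(100, -100)), 1, 2), 1e-10)
  expect_error(domain_loss(rbind(c(0, 0)), 3, 2), "1..C")

  # ordinal loss: worked values
  expect_equal(ordinal_loss(0, 0, 2, 2), log(2))
  expect_equal(ordinal_loss(0, c(1, -1), 3, 3),
               -(log(1 / (1 + exp(-1))) + log(1 / (1 + exp(1)))))
  expect_lt(ordinal_loss(50, c(1, -1), 3, 3), 1e-10)   # a -> +inf, y = L
  expect_error(ordinal_loss(0, c(1, -1), 4, 3), "1..L")
})

test_that("losses equal their brute-force loop oracles on random batches", {
  set.seed(101)
  for (i in 1:5) {
    n <- 20
    pred <- matrix(runif(n * 2), n, 2)
    truth <- matrix(runif(n * 2), n, 2)
    expect_equal(coord_loss(pred, truth), naive_coord_loss(pred, truth),
                 tolerance = 1e-10)

    ell <- cbind(matrix(runif(n * 2), n, 2), matrix(runif(n * 2, 0.05, 0.5), n, 2))
    alpha <- runif(1, 0.5, 0.99)
    expect_equal(ellipse_loss(ell, truth, alpha),
                 naive_ellipse_loss(ell, truth, alpha), tolerance = 1e-10)

    C <- 4
    sc <- matrix(rnorm(n * C), n, C)
    lab <- sample(C, n, TRUE)
    expect_equal(domain_loss(sc, lab, C), naive_domain_loss(sc, lab, C),
                 tolerance = 1e-10)

    L <- 5
    a <- rnorm(n); b <- sort(rnorm(L - 1), decreasing = TRUE)
    lab <- sample(L, n, TRUE)
    expect_equal(ordinal_loss(a, b, lab, L), naive_ordinal_loss(a, b, lab, L),
                 tolerance = 1e-10)
    expect_gte(ordinal_loss(a, b, lab, L), 0)
  }
})

test_that("ordinal probabilities are a valid, telescoping distribution", {
  expect_equal(ordinal_probabilities(0, 0, 2), c(0.5, 0.5))
  set.seed(55)
  for (i in 1:10) {
    L <- sample(3:7, 1)
    b <- sort(rnorm(L - 1, sd = 2), decreasing = TRUE)
    a <- rnorm(4)
    P <- ordinal_probabilities(a, b, L)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
    expect_true(all(P >= -1e-12))
    # cumulative P(y > l) non-increasing in l
    surv <- t(apply(P, 1, function(p) rev(cumsum(rev(p)))))[, -1, drop = FALSE]
    expect_true(all(diff(t(surv)) <= 1e-12))
  }
  # extreme score concentrates mass on the first layer
  expect_gt(ordinal_probabilities(-50, c(1, -1), 3)[1], 1 - 1e-10)
  expect_error(ordinal_probabilities(0, c(-1, 1), 3), "non-increasing")
})

test_that("the coordinate scaler is an exact affine bijection on the training range", {
  set.seed(9)
  co <- cbind(runif(40, -3, 7), runif(40, 100, 250))
  sc <- fit_coord_scaler(co)
  z <- scale_coords(co, sc)
  expect_true(all(z >= 0 & z <= 1))
  expect_equal(unscale_coords(z, sc), co, tolerance = 1e-12)
  expect_equal(scale_coords(rbind(sc$min), sc), rbind(c(0, 0)),
               ignore_attr = TRUE)
  expect_equal(scale_coords(rbind(sc$max), sc), rbind(c(1, 1)),
               ignore_attr = TRUE)
  expect_equal(scale_coords(rbind((sc$min + sc$max) / 2), sc),
               rbind(c(0.5, 0.5)), ignore_attr = TRUE)
  expect_error(fit_coord_scaler(cbind(rep(1, 5), 1:5)), "degenerate")
})

test_that("ellipse loss is continuous across the q = 1 boundary", {
  truth <- rbind(c(0.6, 0.5))
  f <- function(r1) ellipse_loss(rbind(c(0.5, 0.5, r1, 0.2)), truth, 0.9)
  # q crosses 1 at r1 = 0.1; bracket it tightly from both sides
  eps <- 1e-7
  expect_lt(abs(f(0.1 - eps) - f(0.1 + eps)), 1e-5)
  expect_equal(f(0.1), 0)
})

test_that("training honors defaults, reduces the loss, and is seed-deterministic", {
  cfg <- location_model_config("coord2d")
  expect_equal(cfg$hidden_sizes, c(50L, 10L, 5L))   # stated default
  expect_equal(cfg$alpha, 0.95)
  expect_error(location_model_config("coord2d", hidden_sizes = integer(0)),
               "hidden_sizes")

  spec <- tissue_spec(grid = c(14, 14), hole_fraction = 0.1, n_layers = 2,
                      genes = gradient_panel(10, 3, seed = 2), seed = 17)
  ref <- normalize_expression(make_reference(spec))
  cfg <- location_model_config("coord2d", epochs = 300, seed = 4)
  m <- train_location_model(ref, config = cfg)
  expect_lt(tail(m$log$loss, 1), 0.1 * m$log$loss[1])  # < 10% of initial

  q <- make_query(spec, 25, 0, seed = 31)
  h <- harmonize_genes(ref, q)
  p1 <- predict(train_location_model(h$reference, config = cfg), h$query)
  p2 <- predict(train_location_model(h$reference, config = cfg), h$query)
  expect_identical(p1$coords, p2$coords)               # determinism
  expect_true(all(p1$coords >= 0 & p1$coords <= 1))    # sigmoid contract

  # task/label mismatch errors
  nolab <- ref; nolab$labels <- NULL
  expect_error(train_location_model(
    nolab, config = location_model_config("ordinal", epochs = 1)), "labels")
  nocoord <- ref; nocoord$spatial_coords <- NULL
  expect_error(train_location_model(
    nocoord, config = location_model_config("coord2d", epochs = 1)),
    "spatial_coords")
})

test_that("replicate rows extend training with the source coordinates", {
  spec <- tissue_spec(grid = c(10, 10), hole_fraction = 0, n_layers = 2,
                      genes = gradient_panel(6, 2, seed = 3), seed = 23)
  ref <- normalize_expression(make_reference(spec))
  fake <- structure(list(
    replicates = list(ref$matrix + rnorm(length(ref$matrix), sd = 0.1)),
    source_fingerprint = "test", seed = 1L), class = "ReplicateSet")
  m <- train_location_model(ref, fake, location_model_config(
    "coord2d", epochs = 5, seed = 1))
  expect_equal(m$n_train, 2 * nrow(ref$matrix))
  bad <- fake
  bad$replicates[[1]] <- bad$replicates[[1]][, -1]
  expect_error(train_location_model(ref, bad, location_model_config(
    "coord2d", epochs = 1)), "replicate shape")
})
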