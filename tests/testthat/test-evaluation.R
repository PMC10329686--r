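test_that("top-k layer accuracy counts exact and adjacent matches under the order", {
  order7 <- c("L1", "L2", "L3", "L4", "L5", "L6", "WM")
  truths <- c("L1", "L2", "L3")
  preds <- c("L2", "L2", "L5")
  expect_equal(topk_layer_accuracy(preds, truths, order7, 1), 1 / 3)
  expect_equal(topk_layer_accuracy(preds, truths, order7, 2), 2 / 3)
  expect_equal(topk_layer_accuracy(truths, truths, order7, 1), 1)
  expect_equal(topk_layer_accuracy(truths, truths, order7, 2), 1)
  # WM is adjacent to L6
  expect_equal(topk_layer_accuracy("WM", "L6", order7, 2), 1)
  expect_error(topk_layer_accuracy("L9", "L1", order7, 1), "outside")

  # top2 >= top1 on random labelings; invariant under order-preserving relabel
  set.seed(12)
  for (i in 1:10) {
    t <- sample(order7, 30, TRUE); p <- sample(order7, 30, TRUE)
    a1 <- topk_layer_accuracy(p, t, order7, 1)
    a2 <- topk_layer_accuracy(p, t, order7, 2)
    expect_gte(a2, a1)
    relab <- stats::setNames(paste0("layer_", seq_along(order7)), order7)
    expect_equal(topk_layer_accuracy(relab[p], relab[t], unname(relab), 2), a2)
  }
})

test_that("pairwise-distance correlation is 1 under isometries and matches brute force", {
  set.seed(2)
  pts <- matrix(runif(20), 10, 2)
  expect_equal(pairwise_distance_correlation(pts, pts), 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- pts %*% R + 3                        # rotation + translation
  expect_equal(pairwise_distance_correlation(moved, pts), 1)
  expect_equal(pairwise_distance_correlation(2.5 * pts, pts), 1)  # scaling
  refl <- pts %*% diag(c(-1, 1))
  expect_equal(pairwise_distance_correlation(refl, pts), 1)

  # 4 hand-picked points vs a distortion: direct 6-pair computation
  a <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2))
  b <- rbind(c(0, 0), c(1, 1), c(1, 0), c(3, 1))
  pairs <- utils::combn(4, 2)
  da <- apply(pairs, 2, function(ij) sqrt(sum((a[ij[1], ] - a[ij[2], ])^2)))
  db <- apply(pairs, 2, function(ij) sqrt(sum((b[ij[1], ] - b[ij[2], ])^2)))
  expect_equal(pairwise_distance_correlation(b, a), cor(db, da),
               tolerance = 1e-12)

  expect_error(pairwise_distance_correlation(matrix(0, 3, 2), pts[1:3, ]),
               "zero variance")
  expect_message(
    r <- pairwise_distance_correlation(pts, pts, max_points = 5),
    "subsampled")
  expect_equal(r, 1)
})

test_that("euclidean errors report per-cell distances and order statistics", {
  expect_equal(euclidean_errors(rbind(c(3, 4)), rbind(c(0, 0)))$errors, 5)
  pts <- matrix(runif(40), 20, 2)
  expect_equal(euclidean_errors(pts, pts)$errors, rep(0, 20))
  set.seed(5)
  pred <- pts + matrix(rnorm(40, sd = 0.2), 20, 2)
  ee <- euclidean_errors(pred, pts)
  direct <- sort(sqrt(rowSums((pred - pts)^2)))
  expect_equal(ee$median, median(direct))     # sort-based oracle
  expect_equal(ee$q1, unname(quantile(direct, 0.25)))
  expect_error(euclidean_errors(pts, pts[1:5, ]), "shape")
})

test_that("recovered expression maps bin means correctly and conserve totals", {
  # single cell at the origin lands in the corner bin only
  m <- recovered_expression_map(rbind(c(0, 0)), 2.5, c(4, 4))
  expect_equal(m[1, 1], 2.5)
  expect_equal(sum(!is.na(m)), 1)
  # two cells sharing a bin hold their mean
  m2 <- recovered_expression_map(rbind(c(0.1, 0.1), c(0.12, 0.14)), c(1, 3),
                                 c(4, 4))
  expect_equal(m2[1, 1], 2)
  # conservation: sum(mean * count) recovers the total signal
  set.seed(8)
  co <- matrix(runif(200), 100, 2)
  v <- rnorm(100)
  m3 <- recovered_expression_map(co, v, c(5, 6))
  cn <- attr(m3, "counts")
  expect_equal(sum(m3 * cn, na.rm = TRUE), sum(v))
  expect_error(recovered_expression_map(co, v, c(1, 5)), "at least 2 x 2")
})

test_that("ssim matches the windowed reference oracle and its fixed points", {
  set.seed(3)
  a <- matrix(rnorm(15 * 12), 15, 12)
  expect_equal(ssim(a, a), 1)
  b <- a + matrix(rnorm(15 * 12, sd = 0.7), 15, 12)
  expect_equal(ssim(a, b), naive_ssim(a, b), tolerance = 1e-6)
  # anti-correlated structure scores negative when windows are mean-free:
  # a stripe pattern with period 7 (the window size) has exactly zero mean
  # in every interior window, isolating the (negative) structure term
  stripes <- matrix(rep(c(3, 2, 1, 0, -1, -2, -3), length.out = 28), 28, 28)
  expect_lt(ssim(stripes, -stripes), 0)
  # pairwise NA exclusion agrees with the oracle too
  aa <- a; bb <- b
  aa[sample(length(aa), 20)] <- NA
  bb[sample(length(bb), 20)] <- NA
  expect_equal(ssim(aa, bb), naive_ssim(aa, bb), tolerance = 1e-6)
  expect_error(ssim(a, b[1:10, ]), "identical shape")
})
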