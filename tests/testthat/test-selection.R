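test_that("the sigmoid transfer binarization behaves at its landmarks", {
  # midpoint: transfer value exactly 0.5
  expect_equal(stats::plogis(8 * (0.5 - 0.5)), 0.5)
  expect_equal(binarize_position(c(0.5, 0.5), rands = c(0.49, 0.51)), c(1L, 0L))

  # deterministic mode thresholds at 0.5
  expect_identical(binarize_position(c(0.9, 0.1, 0.5), mode = "deterministic"),
                   c(1L, 0L, 1L))

  # all-ones position: selection probability S(4) per bit, binomial check
  p <- stats::plogis(4)
  set.seed(1)
  counts <- replicate(1000, sum(binarize_position(rep(1, 50))))
  expect_lt(abs(mean(counts) / 50 - p), 3 * sqrt(p * (1 - p) / (50 * 1000)) + 0.005)

  # all-zero outcome is repaired to exactly one forced bit
  rep_mask <- binarize_position(c(0.1, 0.4, 0.2), rands = rep(1, 3))
  expect_equal(sum(rep_mask), 1L)
  expect_equal(which(rep_mask == 1L), 2L)  # largest transfer value
})

test_that("the fitness function reproduces its worked values and orderings", {
  expect_equal(fitness_value(1.0, 2560, 2560), 0.01)
  expect_equal(fitness_value(1.0, 1, 2560), 0.01 * (1 / 2560))
  expect_equal(fitness_value(0.9, 899, 2560), 0.99 * 0.1 + 0.01 * (899 / 2560))
  expect_equal(fitness_value(0.9, 899, 2560), 0.102512, tolerance = 1e-5)
  expect_error(fitness_value(1, 1, 2, sigma = 1), class = "hawkfs_error_bad_sigma")

  # J stays within [0, 1] across its whole domain
  grid <- expand.grid(acc = seq(0, 1, 0.25), fsl = c(1, 10, 100),
                      sigma = c(0.01, 0.5, 0.99))
  J <- with(grid, mapply(fitness_value, acc, fsl, 100, sigma))
  expect_true(all(J >= 0 & J <= 1))

  # nested masks with equal accuracy: the smaller mask always wins
  expect_lt(fitness_value(0.95, 10, 100), fitness_value(0.95, 60, 100))
  # and lowering sigma widens that gap
  gap <- function(s) fitness_value(0.95, 60, 100, s) - fitness_value(0.95, 10, 100, s)
  expect_lt(gap(0.99), gap(0.5))
})

test_that("KNN classification is exact on separable data and deterministic under ties", {
  sep <- make_separable(n = 40, d = 2, sep = 10)
  sp <- holdout_split(sep, 0.25, seed = 1)
  expect_equal(knn_accuracy(sp$train, sp$test, NULL, k = 1), 1.0)
  expect_equal(knn_accuracy(sep, sep, NULL, k = 1), 1.0)  # memorization

  # permuted labels classify at chance
  set.seed(3)
  ds <- make_dataset(n = 400, d = 10, seed = 3)
  sp <- holdout_split(ds, 0.2, seed = 3)
  acc <- knn_accuracy(sp$train, sp$test, NULL, k = 5)
  expect_gt(acc, 0.42); expect_lt(acc, 0.58)

  expect_error(knn_predict(matrix(0, 3, 1), c(0L, 1L, 0L), matrix(0, 1, 1), k = 4),
               class = "hawkfs_error_k_too_large")

  # distance tie at k = 1: equidistant training points resolve to the lower index
  tr_x <- matrix(c(1, -1), 2, 1)          # both at distance 1 from the query
  expect_equal(knn_predict(tr_x, c(1L, 0L), matrix(0, 1, 1), k = 1), 1L)
  expect_equal(knn_predict(tr_x[2:1, , drop = FALSE], c(0L, 1L),
                           matrix(0, 1, 1), k = 1), 0L)
  # vote tie at k = 2 resolves to the lower label
  expect_equal(knn_predict(matrix(c(0.5, -0.4), 2, 1), c(1L, 0L),
                           matrix(0, 1, 1), k = 2), 0L)

  # cross-check against class::knn on tie-free data
  skip_if_not_installed("class")
  set.seed(4)
  tr <- matrix(rnorm(60), 30, 2); te <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0L, 1L), 15)
  ours <- knn_predict(tr, y, te, k = 3)
  theirs <- as.integer(as.character(class::knn(tr, te, factor(y), k = 3)))
  expect_identical(ours, theirs)
})

test_that("wrapper selection is deterministic with a monotone trace and sane masks", {
  sd_ <- generate_two_view(synthetic_spec(n_samples = 80, d_x = 15, d_y = 10,
                                          n_informative = 3, seed = 6))
  ds <- labeled_dataset(sd_$dataset$view_x, sd_$dataset$labels)
  sp <- holdout_split(ds, 0.2, seed = 6)

  a <- select_features(sp$train, sp$test, n_hawks = 6, max_iters = 8, seed = 9)
  b <- select_features(sp$train, sp$test, n_hawks = 6, max_iters = 8, seed = 9)
  expect_identical(a$mask, b$mask)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(a$holdout_accuracy, b$holdout_accuracy)

  expect_false(is.unsorted(-a$fitness_trace))
  expect_gte(a$n_selected, 1L)
  expect_equal(a$n_selected, sum(a$mask))
  expect_length(a$mask, 15L)
  expect_identical(a$selected_ids, sp$train$view_x$feature_ids[a$mask == 1L])
  # the returned fitness is the best value the trace reaches
  expect_equal(a$fitness, min(a$fitness_trace))

  expect_error(select_features(sd_$dataset), class = "hawkfs_error_two_views")
})

test_that("selection recovers planted signal far above the chance rate", {
  hits <- 0L
  prec <- acc <- numeric(3)
  for (s in 1:3) {
    sd_ <- generate_two_view(synthetic_spec(seed = 20 + s))  # 5 informative of 60
    ds <- labeled_dataset(sd_$dataset$view_x, sd_$dataset$labels)
    sp <- holdout_split(ds, 0.2, seed = 20 + s)
    sel <- select_features(sp$train, sp$test, n_hawks = 15, max_iters = 60,
                           seed = s)
    sel_idx <- which(sel$mask == 1L)
    hits <- hits + any(sd_$informative_mask_x[sel_idx])
    prec[s] <- mean(sd_$informative_mask_x[sel_idx])
    acc[s] <- sel$holdout_accuracy
  }
  expect_equal(hits, 3L)                 # a planted feature in every run
  base_rate <- 5 / 60
  expect_gt(mean(prec), 3 * base_rate)   # strong enrichment of planted features
  expect_gt(mean(acc), 0.85)
})

test_that("inflating the sparsity weight shrinks the selected subset", {
  n99 <- n50 <- numeric(4)
  for (s in 1:4) {
    sd_ <- generate_two_view(synthetic_spec(seed = 30 + s))
    ds <- labeled_dataset(sd_$dataset$view_x, sd_$dataset$labels)
    sp <- holdout_split(ds, 0.2, seed = 30 + s)
    n99[s] <- select_features(sp$train, n_hawks = 8, max_iters = 20,
                              sigma = 0.99, seed = s)$n_selected
    n50[s] <- select_features(sp$train, n_hawks = 8, max_iters = 20,
                              sigma = 0.5, seed = s)$n_selected
  }
  expect_lt(mean(n50), mean(n99))
})
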