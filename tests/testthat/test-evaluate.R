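test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(1, 2), c(1, 2), C = 2)
  expect_equal(unname(diag(cm)), c(1, 1))
  cm <- confusion(c(1, 2), c(2, 1), C = 2)
  expect_equal(unname(cm), matrix(c(0, 1, 1, 0), 2))
  set.seed(51)
  y <- sample(1:5, 1000, replace = TRUE)
  p <- sample(1:5, 1000, replace = TRUE)
  cm <- confusion(y, p, 5)
  expect_equal(unname(rowSums(cm)), unname(tabulate(y, 5)))
  expect_equal(unname(colSums(cm)), unname(tabulate(p, 5)))
  expect_equal(sum(cm), 1000)
  expect_error(confusion(1:3, 1:2, 5), "equal length")
})

test_that("metrics are exact on perfect predictions and order-invariant", {
  cm <- diag(c(10L, 5L, 3L, 2L, 1L))
  dimnames(cm) <- list(true = AAMI_CLASSES, predicted = AAMI_CLASSES)
  pc <- per_class_metrics(cm)
  expect_true(all(unlist(pc[, -1]) == 100))
  expect_true(all(unlist(aggregate_metrics(cm)[, -1]) == 100))
  # permutation invariance
  set.seed(52)
  y <- sample(1:5, 400, replace = TRUE)
  p <- sample(1:5, 400, replace = TRUE)
  o <- sample(400)
  expect_equal(confusion(y, p, 5), confusion(y[o], p[o], 5))
})

test_that("macro is the unweighted mean and aggregate the micro rate", {
  cm <- reference_confusion("intra")
  pc <- per_class_metrics(cm)
  mac <- macro_metrics(pc)
  expect_equal(mac$sensitivity, mean(pc$sensitivity))
  expect_equal(mac$accuracy, mean(pc$accuracy))
  agg <- aggregate_metrics(cm)
  expect_equal(agg$sensitivity, 100 * sum(diag(cm)) / sum(cm))
  # same-rate classes collapse to that rate
  cm2 <- matrix(c(8L, 2L, 2L, 8L), 2, byrow = TRUE)
  dimnames(cm2) <- list(true = c("a", "b"), predicted = c("a", "b"))
  pc2 <- per_class_metrics(cm2)
  expect_equal(macro_metrics(pc2)$sensitivity, 80)
})

test_that("display rounding is half-away-from-zero at two decimals", {
  # 0.625 is exactly representable: half-up gives .63, round-half-even .62
  expect_equal(round_half_up(c(0.625, 86.6646, 1.514)),
               c(0.63, 86.66, 1.51))
  expect_equal(round(0.625, 2), 0.62)
  expect_equal(round_half_up(-0.625), -0.63)
})

test_that("stratified folds partition each class as evenly as possible", {
  labels <- factor(rep(AAMI_CLASSES, times = c(60, 25, 13, 7, 3)),
                   levels = AAMI_CLASSES)
  folds <- make_stratified_folds(labels, k = 5, seed = 9)
  expect_length(folds, length(labels))
  expect_true(all(folds %in% 1:5))
  for (cl in AAMI_CLASSES) {
    sizes <- tabulate(folds[labels == cl], 5)
    expect_lte(diff(range(sizes)), 1)
  }
  # deterministic under the seed
  expect_identical(folds, make_stratified_folds(labels, k = 5, seed = 9))
  expect_error(make_stratified_folds(labels, k = 1), ">= 2")
})

test_that("intra-patient cross-validation pools every sample exactly once", {
  ds <- synthesize_segments(c(120, 40, 40, 20, 6), seed = 61)
  cfg <- model_config(n_classes = 5, conv_blocks = list(c(4, 5, 0)),
                      transition_filters = NULL, pool = c(4, 4),
                      fc_units = 8, fc_dropout = 0, seed = 61)
  res <- run_intra_patient(ds, k = 3, seed = 61, config = cfg,
                           loss = "cs", epochs = 1, batch_size = 64)
  expect_equal(sum(res$confusion), nrow(ds$x))
  expect_equal(unname(rowSums(res$confusion)),
               unname(as.integer(ds$class_counts)))
  expect_s3_class(res$report, "metrics_report")
})

test_that("inter-patient evaluation refuses overlapping record sets", {
  a <- synthesize_segments(c(30, 5, 5, 2, 2), seed = 62, record_id = "recA")
  b <- synthesize_segments(c(30, 5, 5, 2, 2), seed = 63, record_id = "recA")
  expect_error(run_inter_patient(a, b), "protocol error")
})

test_that("paired loss comparison reports both arms and their differences", {
  bench <- imbalanced_benchmark(seed = 64, n_train = 400, n_test = 150)
  cfg <- model_config(n_classes = 5, conv_blocks = list(c(4, 5, 0)),
                      transition_filters = NULL, pool = c(4, 4),
                      fc_units = 8, fc_dropout = 0, seed = 64)
  cmp <- compare_losses(bench$train, bench$test, cfg, epochs = 1,
                        batch_size = 64)
  expect_named(cmp, c("cs", "ce", "delta"))
  expect_equal(cmp$delta$sensitivity,
               cmp$cs$sensitivity - cmp$ce$sensitivity)
  expect_equal(cmp$cs$class, cmp$delta$class)
})
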