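test_that("inverse-frequency class weights behave as balanced weighting", {
  expect_equal(class_weights(c(5, 5)), c(1, 1))
  expect_equal(class_weights(c(8, 2)), c(0.625, 2.5))
  w <- class_weights(c(90, 10))
  expect_equal(w[2] / w[1], 9)
  expect_true(is.na(class_weights(c(3, 0))[2]))
  expect_error(class_weights(c(0, 0)), "positive")
})

test_that("quadratic-mean blending interpolates batch and dataset weights", {
  w <- c(0.5, 1, 2)
  expect_equal(blend_weights(w, w), w)
  expect_equal(blend_weights(0.625, 2.5), sqrt((0.390625 + 6.25) / 2))
  expect_equal(blend_weights(0.625, 2.5), 1.82217, tolerance = 1e-5)
  # power-mean inequality and componentwise bounds
  set.seed(41)
  a <- runif(20, 0, 5); b <- runif(20, 0, 5)
  q <- blend_weights(a, b)
  expect_true(all(q >= (a + b) / 2 - 1e-12))
  expect_true(all(q >= pmin(a, b) & q <= pmax(a, b) + 1e-12))
  expect_error(blend_weights(c(-1, 1), c(1, 1)), "nonnegative")
})

test_that("per-class FPR/FNR follow the one-vs-rest confusion tables", {
  r <- batch_rates(c(1, 2, 1, 2), c(1, 2, 1, 2), 2)
  expect_equal(r$FPR, c(0, 0))
  expect_equal(r$FNR, c(0, 0))
  # hand-counted 2x2: true (1,1,2,2), pred (1,2,2,2)
  r <- batch_rates(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(r$FNR[1], 1 / 2)
  expect_equal(r$FPR[1], 0)
  expect_equal(r$FPR[2], 1 / 2)
  expect_equal(r$FNR[2], 0)
  # degenerate: everything predicted class 1
  r <- batch_rates(c(1, 1, 1, 2), rep(1, 4), 2)
  expect_equal(r$FNR[2], 1)
  expect_equal(r$FPR[1], 1)
  expect_error(batch_rates(1:3, 1:2, 3), "equal length")
})

test_that("harmonic mean of the rates is zero-anchored and bounded", {
  expect_equal(harmonic_cost(0.3, 0.3), 0.3, tolerance = 1e-6)
  expect_equal(harmonic_cost(0.2, 0.1), 2 / (1 / 0.2 + 1 / 0.1),
               tolerance = 1e-6)
  expect_equal(harmonic_cost(0, 0.9), 0)
  expect_equal(harmonic_cost(0.9, 0), 0)
  set.seed(42)
  fpr <- runif(50); fnr <- runif(50)
  hm <- harmonic_cost(fpr, fnr)
  expect_true(all(hm >= 0 & hm <= 1))
  expect_true(all(hm <= pmin(fpr, fnr) * 2))
})

test_that("the misclassification cost is the weight plus the performance term", {
  cw <- c(1.8222, 0.9, 3)
  expect_equal(misclassification_cost(cw, c(0, 0, 0)), cw)
  expect_equal(misclassification_cost(1.8222, 0.1333), 1.9555)
  hm <- c(0.2, 0, 1)
  expect_true(all(misclassification_cost(cw, hm) >= cw))
})

test_that("the weighted loss reduces to cross-entropy and matches hand values", {
  set.seed(43)
  p <- matrix(runif(12), 4, 3)
  p <- p / rowSums(p)
  y <- c(1, 3, 2, 1)
  plain <- -mean(log(p[cbind(1:4, y)]))
  expect_equal(total_loss(p, y, phi = rep(1, 3)), plain, tolerance = 1e-12)
  expect_equal(total_loss(p, y), plain, tolerance = 1e-12)
  # certainty costs nothing
  expect_equal(total_loss(matrix(c(1, 0), 1, 2), 1, c(2, 2)), 0)
  # two samples with p(true) = 0.5 and 0.25 and costs 2 and 1:
  # (2*ln 2 + 1*ln 4)/2 = 2 ln 2
  p2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(total_loss(p2, c(1, 2), phi = c(2, 1)), 2 * log(2),
               tolerance = 1e-12)
  # zero probability at the true label stays finite via the clamp
  expect_true(is.finite(total_loss(matrix(c(0, 1), 1, 2), 1)))
})

test_that("compute_batch_cost equals the brute-force oracle on random batches", {
  set.seed(44)
  for (rep in 1:40) {
    C <- sample(2:5, 1)
    M <- sample(2:16, 1)
    dataset_counts <- sample(1:50, C, replace = TRUE)
    y <- sample(seq_len(C), M, replace = TRUE)
    pred <- sample(seq_len(C), M, replace = TRUE)
    got <- compute_batch_cost(y, pred, dataset_counts, C)
    want <- oracle_batch_cost(y, pred, dataset_counts, C)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12,
                   info = paste("field", f, "rep", rep))
    }
    # structural invariants
    expect_equal(got$phi, got$CW + got$HM_b)
    expect_true(all(got$HM_b >= 0 & got$HM_b <= 1))
    expect_true(all(got$CW >= pmin(got$CW_b, got$CW_D) - 1e-12))
    expect_true(all(got$CW <= pmax(got$CW_b, got$CW_D) + 1e-12))
    expect_true(all(is.finite(got$phi)))
  }
})

test_that("classes absent from a batch fall back to the dataset weight", {
  counts <- c(80, 15, 4, 1)     # class 4 never sampled below
  y <- c(1, 1, 2, 3)
  st <- compute_batch_cost(y, y, counts, 4)
  CW_D4 <- sum(counts) / (4 * counts[4])
  expect_equal(st$CW_b[4], CW_D4)
  expect_equal(st$CW[4], CW_D4)   # quadratic mean of equal values
  expect_true(is.finite(st$phi[4]))
  # single-class batch is finite everywhere
  st1 <- compute_batch_cost(rep(1, 8), rep(1, 8), counts, 4)
  expect_true(all(is.finite(st1$phi)))
})

test_that("shrinking a minority class in the batch never lowers its cost", {
  counts <- c(400, 60, 30, 10)
  pred_of <- function(y) y  # keep performance term fixed at zero
  phi4 <- vapply(c(6, 4, 2, 1), function(n4) {
    y <- c(rep(1, 20), rep(2, 6), rep(3, 4), rep(4, n4))
    compute_batch_cost(y, pred_of(y), counts, 4)$phi[4]
  }, 0)
  expect_true(all(diff(phi4) >= -1e-12))
})

test_that("a balanced batch with perfect predictions on balanced data costs 1", {
  y <- rep(1:4, each = 4)
  st <- compute_batch_cost(y, y, dataset_counts = rep(100, 4), C = 4)
  expect_equal(st$phi, rep(1, 4))
  # and the resulting loss equals plain cross-entropy
  set.seed(45)
  p <- matrix(runif(16 * 4), 16, 4); p <- p / rowSums(p)
  expect_equal(total_loss(p, y, st$phi), total_loss(p, y),
               tolerance = 1e-9)
})

test_that("batch cost states flatten to a fixed-width log row", {
  st <- compute_batch_cost(c(1, 2, 1), c(1, 2, 2), c(10, 5), 2)
  row <- batch_cost_row(st)
  expect_length(row, 7 * 2 + 1)  # 7 per-class vectors + batch size
  expect_true(all(is.finite(row)))
  expect_equal(unname(row["M"]), 3)
})
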