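#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the canonical AAMI
#' order when `C = 5`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors (factors or
#'   integers in `1..C`).
#' @param C Number of classes.
#' @return Integer `C x C` matrix with class dimnames.
#' @export
confusion <- function(true_labels, predicted_labels, C = 5L) {
  y <- .as_class_int(true_labels, C)
  p <- .as_class_int(predicted_labels, C)
  if (length(y) != length(p)) stop("label vectors must have equal length")
  cm <- matrix(0L, C, C)
  for (i in seq_along(y)) cm[y[i], p[i]] <- cm[y[i], p[i]] + 1L
  nm <- if (C == length(AAMI_CLASSES)) AAMI_CLASSES else as.character(seq_len(C))
  dimnames(cm) <- list(true = nm, predicted = nm)
  cm
}

# one-vs-rest TP/TN/FP/FN per class
.ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  data.frame(class = rownames(cm), TP = tp, TN = tn, FP = fp, FN = fn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Display rounding used in the metric tables (2.675 -> 2.68), as opposed to
#' R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-class classification metrics
#'
#' One-vs-rest sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' productivity (precision) `TP/(TP+FP)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` for each class, in percent at full internal
#' precision (round only for display, see [round_half_up()]). A class with
#' no true and no predicted samples has undefined sensitivity/productivity,
#' reported as `NA` and excluded from macro averaging.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Data frame with columns `class`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppr` (percent).
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("confusion matrix is empty")
  k <- .ovr_counts(cm)
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  data.frame(
    class = k$class,
    accuracy = pct(k$TP + k$TN, k$TP + k$TN + k$FP + k$FN),
    sensitivity = pct(k$TP, k$TP + k$FN),
    specificity = pct(k$TN, k$TN + k$FP),
    ppr = pct(k$TP, k$TP + k$FP),
    stringsAsFactors = FALSE
  )
}

#' Macro (unweighted mean) metrics
#'
#' Arithmetic mean of each per-class rate over all classes with defined
#' values.
#'
#' @param per_class Data frame from [per_class_metrics()].
#' @return One-row data frame with the same metric columns.
#' @export
macro_metrics <- function(per_class) {
  data.frame(
    class = "Macro",
    accuracy = mean(per_class$accuracy, na.rm = TRUE),
    sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
    specificity = mean(per_class$specificity, na.rm = TRUE),
    ppr = mean(per_class$ppr, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Aggregate (gross/micro) metrics
#'
#' Rates computed from the classwise-summed one-vs-rest counts
#' (`sum TP`, `sum TN`, `sum FP`, `sum FN`). This is the package's reading of
#' "aggregated" metrics; note that for a square confusion matrix micro
#' sensitivity equals micro positive productivity (both
#' `sum(diag)/total`).
#'
#' @param cm Confusion matrix.
#' @return One-row data frame with the same metric columns.
#' @export
aggregate_metrics <- function(cm) {
  k <- .ovr_counts(cm)
  TP <- sum(k$TP); TN <- sum(k$TN); FP <- sum(k$FP); FN <- sum(k$FN)
  data.frame(
    class = "Aggregate",
    accuracy = 100 * (TP + TN) / (TP + TN + FP + FN),
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    ppr = 100 * TP / (TP + FP),
    stringsAsFactors = FALSE
  )
}

#' Full metrics report for a confusion matrix
#'
#' Per-class rows plus Macro and Aggregate rows, as laid out in the standard
#' AAMI results tables.
#'
#' @param cm Confusion matrix.
#' @param digits If non-NULL, round (half away from zero) for display.
#' @return Data frame of class `metrics_report` with attribute
#'   `confusion`.
#' @export
metrics_report <- function(cm, digits = NULL) {
  pc <- per_class_metrics(cm)
  rep <- rbind(pc, macro_metrics(pc), aggregate_metrics(cm))
  if (!is.null(digits)) {
    num <- vapply(rep, is.numeric, TRUE)
    rep[num] <- lapply(rep[num], round_half_up, digits = digits)
  }
  attr(rep, "confusion") <- cm
  class(rep) <- c("metrics_report", class(rep))
  rep
}

#' Reference confusion matrices from a published MIT-BIH evaluation
#'
#' Confusion matrices reported for a cost-sensitive CNN evaluated on the
#' full MIT-BIH arrhythmia database: the pooled 10-fold intra-patient matrix
#' (100,569 beats) and the inter-patient DS2 test-set matrix (49,632 beats).
#' Bundled so the metric computations can be validated against published
#' full-scale results without the database itself.
#'
#' @param which `"intra"` or `"inter_test"`.
#' @return Integer 5x5 confusion matrix in AAMI class order.
#' @export
reference_confusion <- function(which = c("intra", "inter_test")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reference_confusion_", which, ".csv"),
                   package = "ecgcsl", mustWork = TRUE)
  m <- as.matrix(utils::read.csv(f, row.names = 1L))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = AAMI_CLASSES, predicted = AAMI_CLASSES)
  m
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that within every class the
#' fold sizes differ by at most one. Deterministic given the seed.
#'
#' @param labels Label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold vector in `1..k`, same length as `labels`.
#' @export
make_stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  y <- as.factor(labels)
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    ix <- which(y == cl)
    if (!length(ix)) next
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

#' Intra-patient evaluation: stratified 10-fold cross-validation
#'
#' Beat-wise stratified k-fold over the pooled dataset (beats from every
#' record appear in both training and test folds, which is what the
#' intra-patient paradigm means). Each fold's model is trained on the other
#' k-1 folds and its test predictions accumulated into one pooled confusion
#' matrix, from which the metrics are computed. Classes too rare to appear
#' in every fold (Q) are folded best-effort and assessed on the pooled
#' matrix only.
#'
#' @param dataset A `segment_dataset`.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and all training randomness.
#' @param config A [model_config()] for the per-fold models.
#' @param loss,epochs,batch_size,lr Passed to [train_classifier()].
#' @return List with `report` ([metrics_report()]), `confusion` (pooled
#'   matrix), `folds`.
#' @export
run_intra_patient <- function(dataset, k = 10L, seed = 1L,
                              config = model_config(), loss = "cs",
                              epochs = 10L, batch_size = 128L, lr = 0.01) {
  stopifnot(inherits(dataset, "segment_dataset"))
  folds <- make_stratified_folds(dataset$labels, k = k, seed = seed)
  C <- config$n_classes
  pooled <- matrix(0L, C, C)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (!length(te)) next
    ds_tr <- segment_dataset(dataset$x[tr, , drop = FALSE],
                             dataset$labels[tr],
                             record_id = dataset$meta$record_id[tr],
                             beat_index = dataset$meta$beat_index[tr])
    cfg <- config; cfg$seed <- config$seed + f
    fit <- train_classifier(ds_tr, cfg, loss = loss, epochs = epochs,
                            batch_size = batch_size, lr = lr)
    pred <- predict_class(fit$net, dataset$x[te, , drop = FALSE])
    pooled <- pooled + confusion(dataset$labels[te], pred, C)
  }
  nm <- if (C == length(AAMI_CLASSES)) AAMI_CLASSES else as.character(seq_len(C))
  dimnames(pooled) <- list(true = nm, predicted = nm)
  list(report = metrics_report(pooled), confusion = pooled, folds = folds)
}

#' Inter-patient evaluation: train on DS1, test on DS2
#'
#' Trains one model on the training-split segments and evaluates it once on
#' the held-out patients' segments. The record sets of the two splits must be
#' disjoint; overlap is a protocol error. Reports metrics for both the
#' training set and the test set.
#'
#' @param train,test `segment_dataset`s from disjoint record sets.
#' @param config A [model_config()].
#' @param loss,epochs,batch_size,lr Passed to [train_classifier()].
#' @return List with `train` and `test` [metrics_report()]s, the two
#'   confusion matrices, and the fitted model.
#' @export
run_inter_patient <- function(train, test, config = model_config(),
                              loss = "cs", epochs = 10L, batch_size = 128L,
                              lr = 0.01) {
  stopifnot(inherits(train, "segment_dataset"),
            inherits(test, "segment_dataset"))
  tr_ids <- unique(stats::na.omit(train$meta$record_id))
  te_ids <- unique(stats::na.omit(test$meta$record_id))
  if (length(intersect(tr_ids, te_ids))) {
    stop("protocol error: records present in both train and test splits: ",
         paste(intersect(tr_ids, te_ids), collapse = ", "))
  }
  fit <- train_classifier(train, config, loss = loss, epochs = epochs,
                          batch_size = batch_size, lr = lr)
  C <- config$n_classes
  cm_tr <- confusion(train$labels, predict_class(fit$net, train$x), C)
  cm_te <- confusion(test$labels, predict_class(fit$net, test$x), C)
  list(train = metrics_report(cm_tr), test = metrics_report(cm_te),
       confusion_train = cm_tr, confusion_test = cm_te, fit = fit)
}

#' Compare the cost-sensitive loss against plain cross-entropy
#'
#' Trains two arms of the identical architecture with identical seeds and
#' schedule — one with the dynamic cost-sensitive loss, one with unweighted
#' cross-entropy — on the same training set, evaluates both on the same test
#' set, and reports the per-metric differences (cost-sensitive minus
#' cross-entropy).
#'
#' @param train,test `segment_dataset`s.
#' @param config A [model_config()]; the same config (and seed) is used for
#'   both arms.
#' @param epochs,batch_size,lr Passed to [train_classifier()].
#' @return List with `cs` and `ce` [metrics_report()]s and `delta`, the
#'   elementwise metric differences.
#' @export
compare_losses <- function(train, test, config = model_config(),
                           epochs = 10L, batch_size = 128L, lr = 0.01) {
  arms <- lapply(c("cs", "ce"), function(l) {
    fit <- train_classifier(train, config, loss = l, epochs = epochs,
                            batch_size = batch_size, lr = lr)
    metrics_report(confusion(test$labels,
                             predict_class(fit$net, test$x),
                             config$n_classes))
  })
  names(arms) <- c("cs", "ce")
  delta <- arms$cs
  num <- vapply(delta, is.numeric, TRUE)
  delta[num] <- arms$cs[num] - arms$ce[num]
  attr(delta, "confusion") <- NULL
  list(cs = arms$cs, ce = arms$ce, delta = delta)
}

#' Multi-seed cost-sensitive efficacy experiment
#'
#' The package's standard protocol for measuring what the cost-sensitive
#' loss buys on imbalanced data: for each seed, draw a fresh desk-scale
#' imbalanced benchmark ([imbalanced_benchmark()]), train the compact model
#' for `epochs` epochs once with the cost-sensitive loss and once with plain
#' cross-entropy (identical seed and schedule), and record the
#' minority-class (S, V, F) macro sensitivity of both arms on the held-out
#' split.
#'
#' @param base_seed Integer; seed for the i-th replicate is
#'   `base_seed + 1000 * i`.
#' @param n_seeds Number of replicates (default 5).
#' @param epochs Training epochs per arm (default 6).
#' @param n_train,n_test Benchmark split sizes.
#' @return Data frame with one row per seed: `seed`, `cs`, `ce`, `delta`
#'   (percent minority sensitivity, cost-sensitive minus cross-entropy).
#' @export
cs_efficacy_experiment <- function(base_seed = 1L, n_seeds = 5L,
                                   epochs = 6L, n_train = 5000L,
                                   n_test = 2000L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    sd <- base_seed + 1000L * i
    bench <- imbalanced_benchmark(seed = sd, n_train = n_train,
                                  n_test = n_test)
    cmp <- compare_losses(bench$train, bench$test,
                          model_config_small(seed = sd), epochs = epochs)
    data.frame(seed = sd,
               cs = minority_sensitivity(cmp$cs),
               ce = minority_sensitivity(cmp$ce))
  })
  out <- do.call(rbind, rows)
  out$delta <- out$cs - out$ce
  out
}

#' Minority-class macro sensitivity
#'
#' Unweighted mean sensitivity over the ectopic/fusion classes (S, V, F) —
#' the quantity the cost-sensitive loss is designed to raise.
#'
#' @param report A [metrics_report()].
#' @return Scalar percent.
#' @export
minority_sensitivity <- function(report) {
  rows <- report$class %in% c("S", "V", "F")
  mean(report$sensitivity[rows], na.rm = TRUE)
}
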