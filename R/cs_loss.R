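#' Inverse-frequency balanced class weights
#'
#' `w_c = total / (C * n_c)`: a class at exactly its balanced share
#' (`n_c = total / C`) gets weight 1, rarer classes get proportionally larger
#' weights. Classes with zero count get `NA`; callers substitute the dataset
#' weight for them (see [compute_batch_cost()]).
#'
#' @param counts Per-class integer counts (length `C`).
#' @param total Total sample count; must equal `sum(counts)` and be positive.
#' @param C Number of classes (defaults to `length(counts)`).
#' @return Numeric weight vector of length `C`.
#' @export
class_weights <- function(counts, total = sum(counts), C = length(counts)) {
  if (total <= 0) stop("total must be positive")
  stopifnot(length(counts) == C, all(counts >= 0), sum(counts) == total)
  w <- total / (C * counts)
  w[counts == 0] <- NA_real_
  w
}

#' Blend batch and dataset class weights by quadratic mean
#'
#' `CW_c = sqrt((CW_b,c^2 + CW_D,c^2) / 2)`. The quadratic mean lies between
#' the two inputs (and at or above their arithmetic mean), so a batch whose
#' class mix drifts from the dataset's still produces a weight anchored to
#' both distributions.
#'
#' @param CW_b Batch class weights (nonnegative).
#' @param CW_D Dataset class weights (nonnegative, same length).
#' @return Blended weight vector `CW`.
#' @export
blend_weights <- function(CW_b, CW_D) {
  stopifnot(length(CW_b) == length(CW_D))
  if (any(CW_b < 0, na.rm = TRUE) || any(CW_D < 0, na.rm = TRUE)) {
    stop("class weights must be nonnegative")
  }
  sqrt((CW_b^2 + CW_D^2) / 2)
}

#' Per-class one-vs-rest false-positive and false-negative rates
#'
#' For each class `c`: `FPR_c = FP / (FP + TN)` over samples whose true class
#' is not `c`, and `FNR_c = FN / (FN + TP)` over samples whose true class is
#' `c`. An empty denominator (no positives, or no negatives) yields 0 for
#' that rate.
#'
#' @param true_labels,predicted_labels Integer class labels in `1..C`
#'   (factors are accepted), equal length.
#' @param C Number of classes.
#' @return List with numeric vectors `FPR` and `FNR`, each of length `C`.
#' @export
batch_rates <- function(true_labels, predicted_labels, C) {
  y <- .as_class_int(true_labels, C)
  p <- .as_class_int(predicted_labels, C)
  if (length(y) != length(p)) stop("label vectors must have equal length")
  FPR <- numeric(C); FNR <- numeric(C)
  for (c in seq_len(C)) {
    pos <- y == c
    fp <- sum(!pos & p == c); tn <- sum(!pos & p != c)
    fn <- sum(pos & p != c);  tp <- sum(pos & p == c)
    FPR[c] <- if (fp + tn > 0) fp / (fp + tn) else 0
    FNR[c] <- if (fn + tp > 0) fn / (fn + tp) else 0
  }
  list(FPR = FPR, FNR = FNR)
}

.as_class_int <- function(x, C) {
  x <- if (is.factor(x)) as.integer(x) else as.integer(x)
  if (length(x) && (min(x) < 1L || max(x) > C)) {
    stop("labels must lie in 1..", C)
  }
  x
}

#' Harmonic mean of the per-class FPR and FNR
#'
#' `HM_c = ((FPR_c^-1 + FNR_c^-1) / 2)^-1`, evaluated with an epsilon-smoothed
#' reciprocal; when either rate is 0 the continuous limit `HM_c = 0` is
#' returned, so a class with no errors of one kind incurs no performance
#' penalty. The harmonic mean is dominated by the smaller rate, which keeps a
#' single inflated rate from dominating the cost.
#'
#' @param FPR,FNR Numeric vectors in `[0, 1]`, same length.
#' @param eps Smoothing constant inside the reciprocals.
#' @return Numeric vector `HM_b` in `[0, 1]`.
#' @export
harmonic_cost <- function(FPR, FNR, eps = 1e-7) {
  stopifnot(length(FPR) == length(FNR),
            all(FPR >= 0 & FPR <= 1), all(FNR >= 0 & FNR <= 1))
  hm <- 2 / (1 / (FPR + eps) + 1 / (FNR + eps))
  hm[FPR == 0 | FNR == 0] <- 0
  pmin(hm, 1)  # smoothing can exceed 1 by eps when both rates are 1
}

#' Per-class misclassification cost
#'
#' `phi = CW + HM_b`: the blended class weight (data-distribution term) plus
#' the FPR/FNR harmonic mean (model-performance term).
#'
#' @param CW Blended class weights from [blend_weights()].
#' @param HM_b Harmonic-mean cost from [harmonic_cost()].
#' @return Numeric cost vector `phi`, componentwise `>= CW`.
#' @export
misclassification_cost <- function(CW, HM_b) {
  stopifnot(length(CW) == length(HM_b), all(HM_b >= 0 & HM_b <= 1))
  CW + HM_b
}

#' Cost-weighted cross-entropy loss
#'
#' `loss = mean_i phi[y_i] * (-log p_i[y_i])` with natural logarithm;
#' probabilities are clamped below at `eps` so the loss is always finite.
#' With `phi` identically 1 this is the plain mean cross-entropy. `phi` is a
#' batch statistic and carries no gradient.
#'
#' @param probabilities Numeric matrix, one row per sample, rows summing
#'   to 1.
#' @param labels True class labels in `1..C` (C = `ncol(probabilities)`).
#' @param phi Per-class cost vector of length C (default: all 1).
#' @param eps Probability clamp.
#' @return Scalar loss.
#' @export
total_loss <- function(probabilities, labels, phi = NULL, eps = 1e-12) {
  probabilities <- as.matrix(probabilities)
  C <- ncol(probabilities)
  y <- .as_class_int(labels, C)
  stopifnot(nrow(probabilities) == length(y))
  if (is.null(phi)) phi <- rep(1, C)
  stopifnot(length(phi) == C)
  p_true <- probabilities[cbind(seq_along(y), y)]
  mean(phi[y] * -log(pmax(p_true, eps)))
}

#' Compute the full per-batch cost state
#'
#' Composes the pieces of the dynamic cost-sensitive loss for one mini-batch:
#' batch class weights `CW_b` (inverse-frequency on the batch), dataset class
#' weights `CW_D` (inverse-frequency on the whole training set), their
#' quadratic-mean blend `CW`, the one-vs-rest `FPR`/`FNR` of the model's
#' current predictions on the batch, their harmonic mean `HM_b`, and the
#' final cost `phi = CW + HM_b`. Classes absent from the batch have no
#' defined batch weight; the dataset weight is substituted (so the blend
#' returns `CW_D` for them). A class absent from the dataset altogether gets
#' weight 0 (it can never occur in a batch).
#'
#' @param batch_labels True labels of the batch, in `1..C`.
#' @param batch_predictions The model's predicted labels for the same batch
#'   (arg-max of the forward pass that produces the loss).
#' @param dataset_counts Per-class counts of the whole training set.
#' @param C Number of classes.
#' @return An object of class `batch_cost_state`: list with `CW_b`, `CW_D`,
#'   `CW`, `FPR`, `FNR`, `HM_b`, `phi`, `M` (batch size).
#' @export
compute_batch_cost <- function(batch_labels, batch_predictions,
                               dataset_counts, C = length(dataset_counts)) {
  y <- .as_class_int(batch_labels, C)
  if (!length(y)) stop("batch must be non-empty")
  stopifnot(length(dataset_counts) == C)
  M <- length(y)
  batch_counts <- tabulate(y, nbins = C)
  CW_D <- class_weights(dataset_counts)
  CW_D[is.na(CW_D)] <- 0
  CW_b <- class_weights(batch_counts, total = M, C = C)
  CW_b[is.na(CW_b)] <- CW_D[is.na(CW_b)]   # dataset prior for absent classes
  CW <- blend_weights(CW_b, CW_D)
  rates <- batch_rates(y, batch_predictions, C)
  HM_b <- harmonic_cost(rates$FPR, rates$FNR)
  phi <- misclassification_cost(CW, HM_b)
  structure(
    list(CW_b = CW_b, CW_D = CW_D, CW = CW, FPR = rates$FPR,
         FNR = rates$FNR, HM_b = HM_b, phi = phi, M = M),
    class = "batch_cost_state"
  )
}

#' @export
print.batch_cost_state <- function(x, ...) {
  m <- rbind(CW_b = x$CW_b, CW_D = x$CW_D, CW = x$CW,
             FPR = x$FPR, FNR = x$FNR, HM_b = x$HM_b, phi = x$phi)
  colnames(m) <- AAMI_CLASSES[seq_len(ncol(m))]
  cat(sprintf("<batch_cost_state> M = %d\n", x$M))
  print(round(m, 4))
  invisible(x)
}

#' Flatten a batch-cost state to one numeric log row
#'
#' @param state A `batch_cost_state`.
#' @return Named numeric vector (`CW_b.1`, ..., `phi.C`, `M`), suitable for
#'   appending to a CSV training log.
#' @export
batch_cost_row <- function(state) {
  stopifnot(inherits(state, "batch_cost_state"))
  fields <- c("CW_b", "CW_D", "CW", "FPR", "FNR", "HM_b", "phi")
  v <- unlist(lapply(fields, function(f) {
    x <- state[[f]]; names(x) <- paste0(f, ".", seq_along(x)); x
  }))
  c(v, M = state$M)
}
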