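#' Train the classifier with SGD
#'
#' Plain stochastic gradient descent (initial learning rate 0.01, L2 weight
#' decay 0.003 on convolution and dense weights) on mini-batches. With
#' `loss = "cs"` the per-class misclassification cost `phi` is recomputed for
#' every batch from its class mix and the model's own predictions on that
#' batch (see [compute_batch_cost()]) and multiplies each sample's
#' cross-entropy; `loss = "ce"` is the conventional unweighted cross-entropy
#' baseline. `phi` is a batch statistic: no gradient flows through it.
#'
#' @param dataset A `segment_dataset` (training data).
#' @param config A [model_config()]; its seed drives weight initialization
#'   and batch shuffling.
#' @param loss `"cs"` (dynamic cost-sensitive) or `"ce"` (cross-entropy).
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param phi_max Optional cap on the per-class cost (default: none).
#' @param log_costs Logical; keep the per-batch cost states (rows of
#'   [batch_cost_row()]) in the result.
#' @param verbose Print per-epoch mean loss.
#' @return A list of class `ecg_fit`: `net`, `loss`, `epoch_loss` (numeric
#'   vector), `cost_log` (matrix or NULL), `class_levels`.
#' @export
train_classifier <- function(dataset, config = model_config(),
                             loss = c("cs", "ce"), epochs = 10L,
                             batch_size = 128L, lr = 0.01,
                             phi_max = NULL, log_costs = FALSE,
                             verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(dataset, "segment_dataset"), epochs >= 1L)
  x <- dataset$x
  y <- as.integer(dataset$labels)
  C <- config$n_classes
  n <- nrow(x)
  dataset_counts <- tabulate(y, nbins = C)
  net <- build_model(config)   # also seeds the RNG stream for shuffling
  epoch_loss <- numeric(epochs)
  cost_log <- if (log_costs) list() else NULL
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = batch_size)
    tot <- 0
    for (s in batch_starts) {
      ix <- ord[s:min(s + batch_size - 1L, n)]
      M <- length(ix)
      xb <- array(x[ix, , drop = FALSE], c(M, ncol(x), 1L))
      yb <- y[ix]
      fw <- .net_forward(net, xb, training = TRUE)
      p <- .softmax(fw$logits)
      if (loss == "cs") {
        preds <- max.col(p, ties.method = "first")
        state <- compute_batch_cost(yb, preds, dataset_counts, C)
        phi <- state$phi
        if (!is.null(phi_max)) phi <- pmin(phi, phi_max)
        if (log_costs) cost_log[[length(cost_log) + 1L]] <-
          batch_cost_row(state)
      } else {
        phi <- rep(1, C)
      }
      tot <- tot + M * total_loss(p, yb, phi)
      onehot <- matrix(0, M, C)
      onehot[cbind(seq_len(M), yb)] <- 1
      dlogits <- (p - onehot) * (phi[yb] / M)
      grads <- .net_backward(net, fw$caches, dlogits)
      net <- .net_update(net, grads, fw$caches, lr, config$l2)
    }
    epoch_loss[ep] <- tot / n
    if (verbose) {
      message(sprintf("epoch %d/%d: mean loss %.4f", ep, epochs,
                      epoch_loss[ep]))
    }
  }
  structure(
    list(net = net, loss = loss, epoch_loss = epoch_loss,
         cost_log = if (log_costs) do.call(rbind, cost_log) else NULL,
         class_levels = levels(dataset$labels)),
    class = "ecg_fit"
  )
}

#' @export
print.ecg_fit <- function(x, ...) {
  cat(sprintf("<ecg_fit> loss=%s, %d epochs, final mean loss %.4f\n",
              x$loss, length(x$epoch_loss),
              x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}
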