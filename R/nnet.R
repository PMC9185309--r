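# 1-D convolutional network with temporal transition modules.
#
# Feature maps are dense arrays of dim (batch, length, channels). Convolution
# is evaluated as an im2col gather followed by one BLAS matrix product, which
# keeps the whole forward/backward pass vectorized in base R.

#' Model configuration
#'
#' Describes the network: a first convolution block followed by max pooling,
#' then alternating temporal transition modules and convolution blocks, a
#' global average pool, a fully connected hidden layer with heavy dropout,
#' and a softmax output. Every convolution block is convolution (same
#' padding) -> batch normalization -> rectifier -> dropout.
#'
#' @param n_classes Number of output classes (default 5, the AAMI classes).
#' @param conv_blocks List of `c(filters, kernel, dropout)` triples, one per
#'   convolution block. Kernels must be odd.
#' @param transition_kernels Kernel sizes of the three parallel transition
#'   branches (default `c(1, 3, 11)`; 15 and 21 are valid alternatives for
#'   the widest branch).
#' @param transition_filters List of per-branch filter counts, one vector per
#'   transition module (one module is placed before each convolution block
#'   after the first). Use `NULL` to omit transition modules entirely (the
#'   plain-CNN ablation baseline).
#' @param pool `c(size, stride)` of the max pool after the first block.
#' @param fc_units Width of the fully connected hidden layer.
#' @param fc_dropout Dropout rate at the fully connected layer (default 0.75,
#'   the ceiling used in the network).
#' @param l2 Weight-decay coefficient applied to convolution and dense
#'   weights (default 0.003).
#' @param seed Integer seed fixing weight initialization.
#' @return A `model_config` list, validated.
#' @export
model_config <- function(n_classes = 5L,
                         conv_blocks = list(c(16, 5, 0.2), c(32, 5, 0.2),
                                            c(64, 5, 0.2)),
                         transition_kernels = c(1L, 3L, 11L),
                         transition_filters = list(c(8, 8, 16), c(16, 16, 32)),
                         pool = c(2L, 2L),
                         fc_units = 64L, fc_dropout = 0.75,
                         l2 = 0.003, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes), conv_blocks = conv_blocks,
              transition_kernels = as.integer(transition_kernels),
              transition_filters = transition_filters,
              pool = as.integer(pool), fc_units = as.integer(fc_units),
              fc_dropout = fc_dropout, l2 = l2, seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "model_config")
}

#' Compact configuration for desk-scale experiments
#'
#' A reduced network (one transition module, 8/16 filters, 32 hidden units)
#' used by the synthetic imbalanced benchmark so that multi-seed training
#' comparisons complete quickly on one CPU.
#'
#' @inheritParams model_config
#' @return A `model_config`.
#' @export
model_config_small <- function(n_classes = 5L, seed = 1L) {
  model_config(n_classes = n_classes,
               conv_blocks = list(c(8, 5, 0.1), c(16, 5, 0.1)),
               transition_filters = list(c(4, 4, 8)),
               pool = c(4L, 4L), fc_units = 32L, seed = seed)
}

.validate_config <- function(cfg) {
  bad <- function(msg) stop("invalid model config: ", msg)
  if (cfg$n_classes < 2L) bad("n_classes must be >= 2")
  for (b in cfg$conv_blocks) {
    if (length(b) != 3L) bad("conv block must be (filters, kernel, dropout)")
    if (b[2] %% 2 != 1 || b[2] < 1) bad("kernel sizes must be odd positive")
    if (b[3] < 0 || b[3] > 0.75) bad("dropout rates must lie in [0, 0.75]")
  }
  if (any(cfg$transition_kernels %% 2L != 1L) ||
      any(cfg$transition_kernels < 1L)) {
    bad("transition kernels must be odd positive")
  }
  if (!is.null(cfg$transition_filters) &&
      length(cfg$transition_filters) > length(cfg$conv_blocks) - 1L) {
    bad("more transition modules than gaps between conv blocks")
  }
  if (cfg$fc_dropout < 0 || cfg$fc_dropout > 0.75) {
    bad("fc_dropout must lie in [0, 0.75]")
  }
  if (cfg$l2 < 0) bad("l2 must be >= 0")
  if (any(cfg$pool < 1L)) bad("pool size and stride must be >= 1")
  invisible(cfg)
}

# ---- layer constructors (He-normal initialization) -------------------------

.he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

.new_conv <- function(in_ch, filters, kernel, dropout = 0) {
  list(type = "conv", k = as.integer(kernel), in_ch = in_ch,
       filters = as.integer(filters), dropout = dropout,
       W = .he_mat(kernel * in_ch, filters, kernel * in_ch),
       b = numeric(filters))
}

.new_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", ch = ch, gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch),
       momentum = momentum, eps = eps)
}

.new_dense <- function(in_dim, units) {
  list(type = "dense", W = .he_mat(in_dim, units, in_dim),
       b = numeric(units))
}

.new_transition <- function(in_ch, kernels, filters) {
  branches <- lapply(seq_along(kernels), function(i) {
    list(conv = .new_conv(in_ch, filters[i], kernels[i]),
         bn = .new_bn(filters[i]))
  })
  list(type = "transition", branches = branches,
       out_ch = sum(filters), filters = as.integer(filters))
}

# ---- primitive forward/backward -------------------------------------------

.im2col <- function(xp, k, L) {
  d <- dim(xp); B <- d[1L]; C <- d[3L]
  blocks <- vector("list", k)
  for (m in seq_len(k)) {
    s <- xp[, m:(m + L - 1L), , drop = FALSE]
    dim(s) <- c(B * L, C)
    blocks[[m]] <- s
  }
  do.call(cbind, blocks)
}

.conv_forward <- function(layer, x) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; C <- d[3L]
  k <- layer$k
  if (k > L) stop("kernel (", k, ") exceeds feature length (", L, ")")
  h <- (k - 1L) %/% 2L
  xp <- array(0, c(B, L + 2L * h, C))
  xp[, (h + 1L):(h + L), ] <- x
  cols <- .im2col(xp, k, L)
  y <- cols %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  dim(y) <- c(B, L, layer$filters)
  list(out = y,
       cache = list(cols = cols, B = B, L = L, C = C, h = h))
}

.conv_backward <- function(layer, cache, dout, need_dx = TRUE) {
  B <- cache$B; L <- cache$L; C <- cache$C; h <- cache$h; k <- layer$k
  dy <- dout
  dim(dy) <- c(B * L, layer$filters)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  if (!need_dx) return(list(dx = NULL, grads = list(W = dW, b = db)))
  dcols <- tcrossprod(dy, layer$W)            # (B*L) x (k*C)
  dxp <- array(0, c(B, L + 2L * h, C))
  for (m in seq_len(k)) {
    blk <- dcols[, ((m - 1L) * C + 1L):(m * C)]
    dim(blk) <- c(B, L, C)
    dxp[, m:(m + L - 1L), ] <- dxp[, m:(m + L - 1L), , drop = FALSE] + blk
  }
  list(dx = dxp[, (h + 1L):(h + L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

.bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- if (length(d) == 3L) matrix(x, d[1L] * d[2L], d[3L]) else x
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  n <- nrow(xm)
  xhat <- (xm - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  out <- if (length(d) == 3L) array(y, d) else y
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, dims = d,
                    mu = mu, v = v, training = training))
}

.bn_backward <- function(layer, cache, dout) {
  d <- cache$dims
  dy <- if (length(d) == 3L) matrix(dout, d[1L] * d[2L], d[3L]) else dout
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(layer$gamma, each = n)
  # dx = invstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (n * dxhat - rep(s1, each = n) - xhat * rep(s2, each = n)) *
    rep(cache$invstd / n, each = n)
  out <- if (length(d) == 3L) array(dx, d) else dx
  list(dx = out, grads = list(gamma = dgamma, beta = dbeta))
}

.bn_update_running <- function(layer, cache) {
  if (!cache$training) return(layer)
  m <- layer$momentum
  layer$run_mean <- m * layer$run_mean + (1 - m) * cache$mu
  layer$run_var <- m * layer$run_var + (1 - m) * cache$v
  layer
}

.relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

.dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

#' Max pooling over the temporal axis
#'
#' `out[i] = max` over the window of size `R` starting at `1 + (i-1)*T`;
#' output length is `floor((L - R)/T) + 1`.
#'
#' @param features Numeric vector, or array of dim (batch, length, channels).
#' @param R Pooling window size.
#' @param T Stride.
#' @return Pooled object of the same kind as the input.
#' @export
max_pool <- function(features, R = 2L, T = 2L) {
  vec <- is.null(dim(features))
  x <- if (vec) array(features, c(1L, length(features), 1L)) else features
  out <- .pool_forward(x, R, T)$out
  if (vec) as.numeric(out) else out
}

.pool_forward <- function(x, R, T) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; C <- d[3L]
  stopifnot(R >= 1L, T >= 1L)
  if (R > L) stop("pooling size (", R, ") exceeds feature length (", L, ")")
  Lo <- (L - R) %/% T + 1L
  starts <- T * (seq_len(Lo) - 1L)      # 0-based window starts
  best <- x[, starts + 1L, , drop = FALSE]
  argr <- array(1L, c(B, Lo, C))        # winning offset within each window
  for (r in seq_len(R)[-1L]) {
    xs <- x[, starts + r, , drop = FALSE]
    upd <- xs > best
    best[upd] <- xs[upd]
    argr[upd] <- r
  }
  list(out = best, cache = list(argr = argr, starts = starts, dims = d))
}

.pool_backward <- function(cache, dout) {
  d <- cache$dims; B <- d[1L]; L <- d[2L]; C <- d[3L]
  Lo <- length(cache$starts)
  lvec <- rep(rep.int(cache$starts, rep.int(B, Lo)), C)   # 0-based starts
  cvec <- rep(seq_len(C) - 1L, each = B * Lo)
  flat <- rep_len(seq_len(B), B * Lo * C) +
    (lvec + as.vector(cache$argr) - 1L) * B + cvec * (B * L)
  dx <- numeric(B * L * C)
  # windows may overlap (stride < size): accumulate where needed
  if (anyDuplicated(flat)) {
    acc <- rowsum(as.vector(dout), flat, reorder = FALSE)
    dx[as.integer(rownames(acc))] <- acc
  } else {
    dx[flat] <- as.vector(dout)
  }
  array(dx, d)
}

# ---- network assembly ------------------------------------------------------

#' Build the classifier network
#'
#' Instantiates all layers of the architecture described by a
#' [model_config()], with weights initialized deterministically from
#' `config$seed`. The network accepts length-400 single-channel segments and
#' emits class probabilities.
#'
#' @param config A `model_config`.
#' @return An object of class `ecg_net`.
#' @export
build_model <- function(config) {
  .validate_config(config)
  set.seed(config$seed)
  layers <- list()
  push <- function(l) layers[[length(layers) + 1L]] <<- l
  in_ch <- 1L
  n_tt <- if (is.null(config$transition_filters)) 0L
          else length(config$transition_filters)
  for (i in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[i]]
    if (i >= 2L && (i - 1L) <= n_tt) {
      tt <- .new_transition(in_ch, config$transition_kernels,
                            config$transition_filters[[i - 1L]])
      push(tt)
      in_ch <- tt$out_ch
    }
    push(.new_conv(in_ch, blk[1], blk[2], blk[3]))
    push(.new_bn(blk[1]))
    push(list(type = "relu"))
    push(list(type = "dropout", rate = blk[3]))
    in_ch <- as.integer(blk[1])
    if (i == 1L) push(list(type = "pool", R = config$pool[1L],
                           T = config$pool[2L]))
  }
  push(list(type = "gap"))
  push(.new_dense(in_ch, config$fc_units))
  push(list(type = "relu"))
  push(list(type = "dropout", rate = config$fc_dropout))
  push(.new_dense(config$fc_units, config$n_classes))
  structure(list(layers = layers, config = config), class = "ecg_net")
}

#' Number of trainable parameters
#' @param net An `ecg_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  count <- function(l) {
    switch(l$type,
      conv = length(l$W) + length(l$b),
      dense = length(l$W) + length(l$b),
      bn = length(l$gamma) + length(l$beta),
      transition = sum(vapply(l$branches, function(b) {
        length(b$conv$W) + length(b$conv$b) +
          length(b$bn$gamma) + length(b$bn$beta)
      }, 0)),
      0L)
  }
  sum(vapply(net$layers, count, 0))
}

#' @export
print.ecg_net <- function(x, ...) {
  types <- vapply(x$layers, `[[`, "", "type")
  cat(sprintf("<ecg_net> %d layers (%s), %d parameters\n",
              length(types), paste(types, collapse = "-"), n_parameters(x)))
  invisible(x)
}

.net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    res <- switch(l$type,
      conv = .conv_forward(l, x),
      bn = .bn_forward(l, x, training),
      relu = .relu_forward(x),
      dropout = .dropout_forward(x, l$rate, training),
      pool = .pool_forward(x, l$R, l$T),
      gap = {
        d <- dim(x)
        out <- vapply(seq_len(d[3L]), function(c)
          rowSums(x[, , c, drop = FALSE], dims = 1L) / d[2L],
          numeric(d[1L]))
        if (is.null(dim(out))) dim(out) <- c(d[1L], d[3L])
        list(out = out, cache = d)
      },
      dense = list(out = sweep(x %*% l$W, 2L, l$b, "+"),
                   cache = x),
      transition = .transition_forward(l, x, training),
      stop("unknown layer type: ", l$type))
    x <- res$out
    caches[i] <- list(res$cache)  # keep NULL placeholders in position
  }
  list(logits = x, caches = caches)
}

.transition_forward <- function(layer, x, training) {
  outs <- list(); bcaches <- list()
  for (j in seq_along(layer$branches)) {
    br <- layer$branches[[j]]
    cv <- .conv_forward(br$conv, x)
    bn <- .bn_forward(br$bn, cv$out, training)
    rl <- .relu_forward(bn$out)
    outs[[j]] <- rl$out
    bcaches[[j]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  }
  d <- dim(outs[[1L]])
  out <- array(0, c(d[1L], d[2L], layer$out_ch))
  off <- 0L
  for (j in seq_along(outs)) {
    f <- layer$filters[j]
    out[, , (off + 1L):(off + f)] <- outs[[j]]
    off <- off + f
  }
  list(out = out, cache = bcaches)
}

.transition_backward <- function(layer, cache, dout) {
  grads <- vector("list", length(layer$branches))
  dx <- NULL
  off <- 0L
  for (j in seq_along(layer$branches)) {
    f <- layer$filters[j]
    dbr <- dout[, , (off + 1L):(off + f), drop = FALSE]
    off <- off + f
    c_j <- cache[[j]]
    dbr <- dbr * c_j$relu
    bnb <- .bn_backward(layer$branches[[j]]$bn, c_j$bn, dbr)
    cvb <- .conv_backward(layer$branches[[j]]$conv, c_j$conv, bnb$dx)
    grads[[j]] <- list(conv = cvb$grads, bn = bnb$grads)
    dx <- if (is.null(dx)) cvb$dx else dx + cvb$dx
  }
  list(dx = dx, grads = grads)
}

.net_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  dx <- dlogits
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    res <- switch(l$type,
      conv = .conv_backward(l, caches[[i]], dx, need_dx = i > 1L),
      bn = .bn_backward(l, caches[[i]], dx),
      relu = list(dx = dx * caches[[i]], grads = NULL),
      dropout = {
        if (!is.null(caches[[i]])) dx <- dx * caches[[i]]
        list(dx = dx, grads = NULL)
      },
      pool = list(dx = .pool_backward(caches[[i]], dx), grads = NULL),
      gap = {
        d <- caches[[i]]
        dd <- array(0, d)
        for (c in seq_len(d[3L])) dd[, , c] <- dx[, c] / d[2L]
        list(dx = dd, grads = NULL)
      },
      dense = list(dx = tcrossprod(dx, l$W),
                   grads = list(W = crossprod(caches[[i]], dx),
                                b = colSums(dx))),
      transition = .transition_backward(l, caches[[i]], dx))
    dx <- res$dx
    grads[i] <- list(res$grads)   # keep NULL placeholders in position
  }
  grads
}

.net_update <- function(net, grads, caches, lr, l2) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    g <- grads[[i]]
    if (l$type %in% c("conv", "dense")) {
      l$W <- l$W - lr * (g$W + l2 * l$W)
      l$b <- l$b - lr * g$b
    } else if (l$type == "bn") {
      l$gamma <- l$gamma - lr * g$gamma
      l$beta <- l$beta - lr * g$beta
      l <- .bn_update_running(l, caches[[i]])
    } else if (l$type == "transition") {
      for (j in seq_along(l$branches)) {
        br <- l$branches[[j]]
        br$conv$W <- br$conv$W - lr * (g[[j]]$conv$W + l2 * br$conv$W)
        br$conv$b <- br$conv$b - lr * g[[j]]$conv$b
        br$bn$gamma <- br$bn$gamma - lr * g[[j]]$bn$gamma
        br$bn$beta <- br$bn$beta - lr * g[[j]]$bn$beta
        br$bn <- .bn_update_running(br$bn, caches[[i]][[j]]$bn)
        l$branches[[j]] <- br
      }
    }
    net$layers[[i]] <- l
  }
  net
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Save and restore a model checkpoint
#'
#' The network (weights, running batch-norm statistics and configuration) is
#' serialized with R's native RDS format; the architecture description is
#' additionally written as a YAML sidecar (`<path>.yaml`) for inspection.
#'
#' @param net An `ecg_net`.
#' @param path Checkpoint file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "ecg_net"))
  saveRDS(net, path)
  yaml::write_yaml(unclass(net$config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `ecg_net`.
#' @export
load_model <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "ecg_net"))
  net
}

#' Same-padding 1-D convolution
#'
#' The linear part of a convolution block: for each output position the dot
#' product of the weight matrix with the zero-padded input window, plus bias.
#' Weight rows are ordered offset-major (offset 1 channels `1..C`, then
#' offset 2, ...). Exposed for direct evaluation against hand-set weights.
#'
#' @param features Numeric vector (single channel) or array of dim
#'   (batch, length, channels).
#' @param W Weight matrix of dim `(kernel * channels) x filters`.
#' @param b Bias vector of length `filters` (default 0).
#' @return Array of dim (batch, length, filters); a plain vector in, single
#'   filter -> vector out.
#' @export
conv_same <- function(features, W, b = numeric(ncol(W))) {
  vec <- is.null(dim(features))
  x <- if (vec) array(features, c(1L, length(features), 1L)) else features
  k <- nrow(W) / dim(x)[3L]
  if (k != round(k)) stop("nrow(W) must be kernel * channels")
  layer <- list(type = "conv", k = as.integer(k), in_ch = dim(x)[3L],
                filters = ncol(W), W = W, b = b)
  out <- .conv_forward(layer, x)$out
  if (vec && ncol(W) == 1L) as.numeric(out) else out
}

#' Create a convolution block
#'
#' One block = convolution (same padding) -> batch normalization ->
#' rectifier -> dropout, the repeating unit of the network.
#'
#' @param in_ch Input channel count.
#' @param filters Number of convolution filters.
#' @param kernel Odd kernel size.
#' @param dropout Dropout rate in `[0, 0.75]`.
#' @return A block object usable with [conv_block()].
#' @export
conv_block_new <- function(in_ch, filters, kernel, dropout = 0) {
  stopifnot(kernel %% 2 == 1, dropout >= 0, dropout <= 0.75)
  list(conv = .new_conv(in_ch, filters, kernel, dropout),
       bn = .new_bn(filters), dropout = dropout)
}

#' Apply a convolution block
#'
#' @param features Array of dim (batch, length, channels).
#' @param block A block from [conv_block_new()].
#' @param training Logical; use batch statistics and sample dropout masks.
#' @return Array of dim (batch, length, filters).
#' @export
conv_block <- function(features, block, training = FALSE) {
  cv <- .conv_forward(block$conv, features)
  bn <- .bn_forward(block$bn, cv$out, training)
  rl <- .relu_forward(bn$out)
  .dropout_forward(rl$out, block$dropout, training)$out
}

#' Create a temporal transition module
#'
#' Three parallel convolution branches with different kernel sizes (default
#' 1/3/11), each followed by batch normalization and a rectifier; branch
#' outputs are concatenated along the channel axis. The mixed kernel widths
#' let one level of the network see both short-range (QRS-scale) and
#' long-range (wave-to-wave) beat morphology.
#'
#' @param in_ch Input channel count.
#' @param kernels Odd kernel sizes, one per branch.
#' @param filters Filter counts, one per branch.
#' @return A transition-module object.
#' @export
transition_module <- function(in_ch, kernels = c(1L, 3L, 11L),
                              filters = c(8L, 8L, 16L)) {
  stopifnot(length(kernels) == length(filters), all(kernels %% 2 == 1))
  .new_transition(as.integer(in_ch), as.integer(kernels),
                  as.integer(filters))
}

#' Apply a temporal transition module
#'
#' @param features Array of dim (batch, length, channels); the length must be
#'   at least the largest branch kernel.
#' @param module A module from [transition_module()].
#' @param training Logical; use batch statistics in the normalization layers.
#' @return Array of dim (batch, length, sum(filters)).
#' @export
temporal_transition <- function(features, module, training = FALSE) {
  .transition_forward(module, features, training)$out
}

#' Class probabilities for a batch of segments
#'
#' Forward pass in evaluation mode (dropout off, batch norm using running
#' statistics); rows sum to 1.
#'
#' @param net A trained or freshly built `ecg_net`.
#' @param x Numeric matrix of segments (rows) or a single segment vector.
#' @param chunk Segments per forward pass (bounds peak memory).
#' @return Matrix of class probabilities, one row per segment.
#' @export
predict_proba <- function(net, x, chunk = 512L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- NULL
  for (s in seq(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    xa <- array(x[ix, , drop = FALSE], c(length(ix), ncol(x), 1L))
    p <- .softmax(.net_forward(net, xa, training = FALSE)$logits)
    out <- if (is.null(out)) p else rbind(out, p)
  }
  out
}

#' Predicted class labels
#'
#' @inheritParams predict_proba
#' @return Factor of AAMI class labels (or integer indices when the network
#'   has a non-standard class count).
#' @export
predict_class <- function(net, x) {
  p <- predict_proba(net, x)
  idx <- max.col(p, ties.method = "first")
  if (ncol(p) == length(AAMI_CLASSES)) {
    factor(AAMI_CLASSES[idx], levels = AAMI_CLASSES)
  } else idx
}
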