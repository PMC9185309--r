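test_that("same-padding convolution matches the brute-force oracle", {
  set.seed(21)
  x <- array(rnorm(2 * 15 * 3), c(2, 15, 3))
  W <- matrix(rnorm(3 * 3 * 4), 9, 4)  # kernel 3, 3 channels, 4 filters
  b <- rnorm(4)
  expect_equal(conv_same(x, W, b), oracle_conv_same(x, W, b),
               tolerance = 1e-12)
  # single-channel vector path, hand-set weights
  v <- c(1, 2, 3, 4, 5)
  Wk <- matrix(c(1, 0, -1), 3, 1)   # difference kernel
  expect_equal(conv_same(v, Wk),
               as.numeric(oracle_conv_same(array(v, c(1, 5, 1)), Wk, 0)))
  # all-zero input with zero bias stays zero through the linear map
  expect_equal(as.numeric(conv_same(array(0, c(1, 8, 1)),
                                    matrix(rnorm(3)), 0)),
               rep(0, 8))
})

test_that("convolution blocks preserve length and kernel bounds are enforced", {
  set.seed(22)
  blk <- conv_block_new(2, 6, 5, dropout = 0)
  x <- array(rnorm(3 * 40 * 2), c(3, 40, 2))
  out <- conv_block(x, blk, training = TRUE)
  expect_equal(dim(out), c(3, 40, 6))
  expect_true(all(out >= 0))  # rectified
  xs <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  expect_error(conv_block(xs, conv_block_new(2, 4, 5)), "exceeds")
})

test_that("max pooling matches brute-force windows", {
  expect_equal(max_pool(c(1, 3, 2, 5), 2, 2), c(3, 5))
  expect_equal(max_pool(rep(4, 10), 3, 2), rep(4, 4))
  v <- rnorm(11)
  expect_equal(max_pool(v, 1, 1), v)
  set.seed(23)
  for (prm in list(c(2, 2), c(3, 1), c(4, 3), c(5, 5))) {
    x <- rnorm(23)
    expect_equal(max_pool(x, prm[1], prm[2]),
                 oracle_max_pool(x, prm[1], prm[2]))
  }
  expect_error(max_pool(rnorm(3), R = 5, T = 1), "exceeds")
})

test_that("pooling gradients route to the arg-max positions", {
  x <- array(c(1, 3, 2, 5, 4, 0), c(1, 6, 1))
  fw <- ecgcsl:::.pool_forward(x, 2L, 2L)
  expect_equal(as.numeric(fw$out), c(3, 5, 4))
  dout <- array(c(10, 20, 30), c(1, 3, 1))
  dx <- ecgcsl:::.pool_backward(fw$cache, dout)
  expect_equal(as.numeric(dx), c(0, 10, 0, 20, 30, 0))
  # overlapping windows accumulate
  fw2 <- ecgcsl:::.pool_forward(array(c(1, 5, 2), c(1, 3, 1)), 2L, 1L)
  dx2 <- ecgcsl:::.pool_backward(fw2$cache, array(c(1, 1), c(1, 2, 1)))
  expect_equal(as.numeric(dx2), c(0, 2, 0))
})

test_that("temporal transition concatenates branch outputs along channels", {
  set.seed(24)
  mod <- transition_module(4, kernels = c(1, 3, 11), filters = c(8, 8, 16))
  x <- array(rnorm(2 * 30 * 4), c(2, 30, 4))
  out <- temporal_transition(x, mod, training = TRUE)
  expect_equal(dim(out), c(2, 30, 32))
  # zeroing the kernel-11 branch leaves the first 16 channels untouched
  mod0 <- mod
  mod0$branches[[3]]$conv$W[] <- 0
  mod0$branches[[3]]$conv$b[] <- 0
  out0 <- temporal_transition(x, mod0, training = TRUE)
  expect_equal(out0[, , 1:16], out[, , 1:16], tolerance = 1e-12)
  expect_true(all(abs(out0[, , 17:32]) < 1e-12))
})

test_that("the assembled network emits valid softmax probabilities deterministically", {
  cfg <- model_config_small(seed = 77)
  net1 <- build_model(cfg)
  net2 <- build_model(cfg)
  expect_identical(net1$layers, net2$layers)   # seed fixes initialization
  expect_gt(n_parameters(net1), 0)
  expect_equal(n_parameters(net1), n_parameters(net2))
  set.seed(31)
  x <- matrix(rnorm(128 * 400), 128, 400)
  p <- predict_proba(net1, x)
  expect_equal(dim(p), c(128, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 128), tolerance = 1e-6)
  # evaluation mode is deterministic (dropout off)
  expect_equal(p, predict_proba(net1, x), tolerance = 1e-12)
  # chunking does not change results
  expect_equal(p, predict_proba(net1, x, chunk = 50L), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(model_config(conv_blocks = list(c(8, 4, 0.1))), "odd")
  expect_error(model_config(conv_blocks = list(c(8, 5, 0.9))), "dropout")
  expect_error(model_config(l2 = -1), "l2")
  expect_error(model_config(fc_dropout = 0.8), "fc_dropout")
  expect_error(model_config(transition_kernels = c(2, 3, 11)), "odd")
})

test_that("removing transition modules yields the plain-CNN ablation", {
  cfg <- model_config(conv_blocks = list(c(4, 3, 0), c(4, 3, 0)),
                      transition_filters = NULL, fc_units = 8, seed = 5)
  net <- build_model(cfg)
  types <- vapply(net$layers, `[[`, "", "type")
  expect_false("transition" %in% types)
  p <- predict_proba(net, matrix(rnorm(3 * 400), 3, 400))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("model checkpoints restore identical predictions", {
  net <- build_model(model_config_small(seed = 33))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(net, f)
  back <- load_model(f)
  x <- matrix(rnorm(5 * 400), 5, 400)
  expect_equal(predict_proba(back, x), predict_proba(net, x),
               tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".yaml")))
})
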