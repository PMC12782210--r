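# Dual-stream transformer: analytic gradients, learning on a constructed
# frequency signature, degeneracies and determinism.

mp <- asNamespace("motionprint")

tiny_cfg <- function(...) {
  transformer_config(sequence_length = 12L, channels = 2L, conv_kernel = 3L,
                     conv_stride = 2L, attention_heads = 2L,
                     encoder_layers = 2L, embedding_dim = 4L, ffn_hidden = 5L,
                     mlp_hidden_sizes = 6L, epochs = 1L, seed = 3L, ...)
}

sinusoid_sequences <- function(n, freq = NULL, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(100 * 6, sd = 0.05), 100, 6)
    if (!is.null(freq)) {
      tt <- (0:99) / 100
      m[, 4] <- m[, 4] + 0.3 * sin(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi))
    }
    m
  })
}

test_that("hand-derived gradients match finite differences", {
  cfg <- tiny_cfg()
  set.seed(42)
  B <- 3
  Xt <- array(rnorm(B * 12 * 2), c(B, 12, 2))
  Xf <- mp$magnitude_spectra(Xt)
  Lf <- dim(Xf)[2]
  It <- mp$conv_index(12L, 3L, 2L)
  If <- mp$conv_index(Lf, 3L, 2L)
  PEt <- mp$positional_encoding(nrow(It), 4L)
  PEf <- mp$positional_encoding(nrow(If), 4L)
  params <- mp$with_seed(1, mp$swipe_init(cfg, Lf))
  y <- c(1, 0, 1)
  loss_fn <- function(p) {
    fw <- mp$swipe_forward(p, Xt, Xf, cfg, It, If, PEt, PEf)
    mp$bce_with_logits(fw$logits, y)$loss
  }
  fw <- mp$swipe_forward(params, Xt, Xf, cfg, It, If, PEt, PEf)
  lb <- mp$bce_with_logits(fw$logits, y)
  gv <- mp$ptree_flatten(mp$swipe_backward(params, fw, cfg, lb$dlogits))
  pv <- mp$ptree_flatten(params)
  eps <- 1e-6
  idx <- sort(sample(length(pv), 60))
  num <- vapply(idx, function(i) {
    pp <- pv; pp[i] <- pp[i] + eps
    pm <- pv; pm[i] <- pm[i] - eps
    (loss_fn(mp$ptree_unflatten(params, pp)) -
       loss_fn(mp$ptree_unflatten(params, pm))) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("the frequency stream detects a 5 Hz signature absent in negatives", {
  tr <- c(sinusoid_sequences(50, 5, seed = 1), sinusoid_sequences(150, NULL, seed = 2))
  te <- c(sinusoid_sequences(30, 5, seed = 3), sinusoid_sequences(90, NULL, seed = 4))
  y_tr <- c(rep(1L, 50), rep(0L, 150))
  y_te <- c(rep(1L, 30), rep(0L, 90))
  m <- fit_swipeformer(tr, y_tr, transformer_config(seed = 11))
  pred <- predict(m, te)
  expect_gte(compute_metrics(y_te, pred$decision)$f1, 0.95)
})

test_that("an untrained transformer predicts near chance", {
  tr <- c(sinusoid_sequences(10, 5, seed = 5), sinusoid_sequences(30, NULL, seed = 6))
  y <- c(rep(1L, 10), rep(0L, 30))
  m <- fit_swipeformer(tr, y, transformer_config(epochs = 0L, seed = 2))
  expect_length(m$fit$history, 0L)
  pred <- predict(m, tr)
  expect_true(all(pred$score > 0.2 & pred$score < 0.8))
  expect_lt(abs(mean(pred$score) - 0.5), 0.25)
})

test_that("training is bit-reproducible from the config seed", {
  tr <- c(sinusoid_sequences(12, 5, seed = 7), sinusoid_sequences(24, NULL, seed = 8))
  y <- c(rep(1L, 12), rep(0L, 24))
  cfg <- transformer_config(epochs = 2L, seed = 13)
  m1 <- fit_swipeformer(tr, y, cfg)
  m2 <- fit_swipeformer(tr, y, cfg)
  expect_identical(m1$fit$history, m2$fit$history)
  expect_identical(predict(m1, tr), predict(m2, tr))
})

test_that("shape mismatches and bad configs are rejected", {
  expect_error(transformer_config(embedding_dim = 10L, attention_heads = 4L),
               "divisible")
  tr <- sinusoid_sequences(6, NULL, seed = 9)
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  m <- fit_swipeformer(tr, y, transformer_config(epochs = 1L, seed = 1))
  short <- lapply(tr, function(s) s[1:50, ])
  expect_error(predict(m, short), "shape")
  expect_error(fit_swipeformer(tr, rep(1L, 6)), "single class")
})
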