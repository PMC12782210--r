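# Compact dual-stream temporal/frequency transformer over raw 1-second
# windows. The temporal stream applies a strided 1-d convolution and a
# self-attention encoder to the 100 x 6 sample sequence; the frequency
# stream applies its own copy of the same stack to the per-channel discrete
# Fourier magnitude spectra; the two mean-pooled embeddings are
# concatenated and classified by a multilayer perceptron with a single
# positive-class (sigmoid) output. Trained end-to-end with Adam on binary
# cross-entropy; gradients are hand-derived (verified against finite
# differences in the test suite).

#' Configuration of the dual-stream transformer
#'
#' @param sequence_length Samples per window (default 100, one second at
#'   100 Hz).
#' @param channels Input channels (6: yaw, pitch, roll, accelX/Y/Z).
#' @param conv_kernel Odd convolution kernel width.
#' @param conv_stride Convolution stride (tokens = floor((L-k)/stride)+1).
#' @param attention_heads,encoder_layers,embedding_dim Encoder shape;
#'   `embedding_dim` must be divisible by `attention_heads`.
#' @param ffn_hidden Width of the encoder's position-wise feed-forward
#'   layer.
#' @param mlp_hidden_sizes Hidden widths of the classifier head.
#' @param epochs Training epochs (0 = leave the network at its random
#'   initialization).
#' @param batch_size,learning_rate Adam minibatch size and step size.
#' @param max_train_windows Cap on training windows; when exceeded, negative
#'   windows are subsampled (seeded) to fit. `Inf` disables the cap. Used
#'   by reduced-scale runs.
#' @param seed Integer seed for initialization, shuffling and subsampling.
#' @return An object of class `transformer_config`.
#' @export
transformer_config <- function(sequence_length = 100L, channels = 6L,
                               conv_kernel = 5L, conv_stride = 2L,
                               attention_heads = 2L, encoder_layers = 1L,
                               embedding_dim = 16L, ffn_hidden = 32L,
                               mlp_hidden_sizes = 32L, epochs = 15L,
                               batch_size = 32L, learning_rate = 3e-3,
                               max_train_windows = Inf, seed = 1L) {
  stopifnot(sequence_length >= 4, channels >= 1, conv_kernel >= 1,
            conv_kernel %% 2 == 1, conv_stride >= 1, attention_heads >= 1,
            encoder_layers >= 1, embedding_dim >= 1, ffn_hidden >= 1,
            all(mlp_hidden_sizes >= 1), epochs >= 0, batch_size >= 1,
            learning_rate > 0)
  if (embedding_dim %% attention_heads != 0)
    stopf("embedding_dim must be divisible by attention_heads")
  structure(as.list(environment()), class = "transformer_config")
}

# ---- stream (conv + encoder + pool) ---------------------------------------

stream_init <- function(L, cfg) {
  d <- cfg$embedding_dim
  Lout <- (L - cfg$conv_kernel) %/% cfg$conv_stride + 1L
  layers <- lapply(seq_len(cfg$encoder_layers), function(i) {
    list(attn = attn_init(d),
         ln1 = list(g = rep(1, d), b = numeric(d)),
         ffn = list(W1 = glorot(d, cfg$ffn_hidden), b1 = numeric(cfg$ffn_hidden),
                    W2 = glorot(cfg$ffn_hidden, d), b2 = numeric(d)),
         ln2 = list(g = rep(1, d), b = numeric(d)))
  })
  list(conv = list(W = glorot(cfg$conv_kernel * cfg$channels, d),
                   b = numeric(d)),
       layers = layers)
}

# Forward over a batch array Xb (B x L x C). Returns pooled embeddings
# (B x d) and the caches needed for the backward pass.
stream_forward <- function(Xb, p, cfg, I, PE) {
  B <- dim(Xb)[1]; Lout <- nrow(I); d <- cfg$embedding_dim
  XC <- matrix(0, B * Lout, ncol(I) * dim(Xb)[3])
  for (b in seq_len(B))
    XC[((b - 1L) * Lout + 1L):(b * Lout), ] <- im2col(Xb[b, , ], I)
  Z0 <- sweep(XC %*% p$conv$W, 2, p$conv$b, "+")
  H <- relu(Z0) + PE[rep(seq_len(Lout), B), ]
  caches <- list(XC = XC, Z0 = Z0, layers = vector("list", length(p$layers)))
  for (li in seq_along(p$layers)) {
    lp <- p$layers[[li]]
    AO <- matrix(0, B * Lout, d)
    attn_caches <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Lout + 1L):(b * Lout)
      af <- attn_forward(H[rows, , drop = FALSE], lp$attn, cfg$attention_heads)
      AO[rows, ] <- af$Y
      attn_caches[[b]] <- af$cache
    }
    R1 <- H + AO
    ln1 <- ln_forward(R1, lp$ln1$g, lp$ln1$b)
    F1 <- sweep(ln1$Y %*% lp$ffn$W1, 2, lp$ffn$b1, "+")
    F1r <- relu(F1)
    F2 <- sweep(F1r %*% lp$ffn$W2, 2, lp$ffn$b2, "+")
    R2 <- ln1$Y + F2
    ln2 <- ln_forward(R2, lp$ln2$g, lp$ln2$b)
    caches$layers[[li]] <- list(attn = attn_caches, ln1 = ln1$cache,
                                ln2 = ln2$cache, H3 = ln1$Y, F1 = F1,
                                F1r = F1r)
    H <- ln2$Y
  }
  E <- rowsum(H, group = rep(seq_len(B), each = Lout)) / Lout
  list(E = E, H = H, caches = caches, B = B, Lout = Lout)
}

stream_backward <- function(fw, p, cfg, dE) {
  B <- fw$B; Lout <- fw$Lout
  dH <- dE[rep(seq_len(B), each = Lout), , drop = FALSE] / Lout
  grads <- list(conv = NULL, layers = vector("list", length(p$layers)))
  for (li in rev(seq_along(p$layers))) {
    lp <- p$layers[[li]]
    lc <- fw$caches$layers[[li]]
    l2b <- ln_backward(lc$ln2, lp$ln2$g, dH)
    dR2 <- l2b$dX
    dF2 <- dR2
    dW2 <- crossprod(lc$F1r, dF2); db2 <- colSums(dF2)
    dF1r <- tcrossprod(dF2, lp$ffn$W2)
    dF1 <- dF1r * (lc$F1 > 0)
    dW1 <- crossprod(lc$H3, dF1); db1 <- colSums(dF1)
    dH3 <- dR2 + tcrossprod(dF1, lp$ffn$W1)
    l1b <- ln_backward(lc$ln1, lp$ln1$g, dH3)
    dR1 <- l1b$dX
    d <- cfg$embedding_dim
    dHl <- dR1
    a_grads <- NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Lout + 1L):(b * Lout)
      ab <- attn_backward(lc$attn[[b]], lp$attn, cfg$attention_heads,
                          dR1[rows, , drop = FALSE])
      dHl[rows, ] <- dHl[rows, , drop = FALSE] + ab$dX
      gb <- ab[c("dWq", "dbq", "dWk", "dbk", "dWv", "dbv", "dWo", "dbo")]
      a_grads <- if (is.null(a_grads)) gb else
        ptree_map2(a_grads, gb, `+`)
    }
    names(a_grads) <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")
    grads$layers[[li]] <- list(attn = a_grads,
                               ln1 = list(g = l1b$dg, b = l1b$db),
                               ffn = list(W1 = dW1, b1 = db1,
                                          W2 = dW2, b2 = db2),
                               ln2 = list(g = l2b$dg, b = l2b$db))
    dH <- dHl
  }
  dZ0 <- dH * (fw$caches$Z0 > 0)
  grads$conv <- list(W = crossprod(fw$caches$XC, dZ0), b = colSums(dZ0))
  grads
}

# ---- whole network ---------------------------------------------------------

swipe_init <- function(cfg, Lf) {
  d <- cfg$embedding_dim
  sizes <- c(2L * d, cfg$mlp_hidden_sizes, 1L)
  list(temporal = stream_init(cfg$sequence_length, cfg),
       frequency = stream_init(Lf, cfg),
       head = mlp_init(sizes))
}

swipe_forward <- function(params, Xt, Xf, cfg, It, If, PEt, PEf) {
  ft <- stream_forward(Xt, params$temporal, cfg, It, PEt)
  ff <- stream_forward(Xf, params$frequency, cfg, If, PEf)
  G <- cbind(ft$E, ff$E)
  hw <- mlp_forward(params$head, G)
  list(logits = hw$logits, ft = ft, ff = ff, G = G, head = hw)
}

swipe_backward <- function(params, fw, cfg, dlogits) {
  hb <- mlp_backward(params$head, fw$head$acts, dlogits)
  dG <- hb$dX
  d <- cfg$embedding_dim
  list(temporal = stream_backward(fw$ft, params$temporal, cfg,
                                  dG[, seq_len(d), drop = FALSE]),
       frequency = stream_backward(fw$ff, params$frequency, cfg,
                                   dG[, d + seq_len(d), drop = FALSE]),
       head = hb$grads)
}

# Per-channel magnitude spectrum of a batch (B x L x C) -> (B x Lf x C),
# Lf = floor(L/2) + 1 (DC through Nyquist; phase discarded).
magnitude_spectra <- function(Xb) {
  B <- dim(Xb)[1]; L <- dim(Xb)[2]; C <- dim(Xb)[3]
  Lf <- L %/% 2 + 1L
  out <- array(0, dim = c(B, Lf, C))
  for (cc in seq_len(C)) {
    # mvfft works column-wise: L x B slab per channel
    slab <- t(Xb[, , cc, drop = TRUE])
    if (B == 1L) slab <- matrix(Xb[1, , cc], L, 1)
    M <- Mod(stats::mvfft(slab))[seq_len(Lf), , drop = FALSE]
    out[, , cc] <- t(M) / L
  }
  out
}

# Per-channel min-max over a batch array; fit on training data only.
fit_channel_minmax <- function(Xb) {
  C <- dim(Xb)[3]
  mins <- maxs <- numeric(C)
  for (cc in seq_len(C)) {
    mins[cc] <- min(Xb[, , cc]); maxs[cc] <- max(Xb[, , cc])
  }
  list(min = mins, max = maxs)
}

apply_channel_minmax <- function(norm, Xb) {
  for (cc in seq_len(dim(Xb)[3])) {
    rng <- norm$max[cc] - norm$min[cc]
    Xb[, , cc] <- if (rng > 0) (Xb[, , cc] - norm$min[cc]) / rng else 0
  }
  Xb
}

as_sequence_array <- function(sequences) {
  if (is.array(sequences) && length(dim(sequences)) == 3L) return(sequences)
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  dims <- vapply(sequences, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all raw window sequences must share one shape")
  out <- array(0, dim = c(length(sequences), dims[1, 1], dims[2, 1]))
  for (i in seq_along(sequences)) out[i, , ] <- sequences[[i]]
  out
}

#' Fit the dual-stream transformer on raw window sequences
#'
#' Sequences are normalized per channel by training-set min-max (both the
#' raw samples and the magnitude spectra, independently), then the network
#' is trained end-to-end with Adam on binary cross-entropy for
#' `cfg$epochs` epochs. With `cfg$epochs = 0` the network keeps its random
#' initialization (predictions near chance). Fully deterministic given
#' `cfg$seed`.
#'
#' @param sequences List of `L x 6` matrices (from
#'   [extract_raw_sequence()]) or a `B x L x 6` array
#'   ([window_raw_sequences()]).
#' @param y Binary labels (1 = target); both classes must be present.
#' @param cfg A [transformer_config()].
#' @param target_user_id Optional identifier recorded on the model.
#' @return A `fitted_model` of kind `"swipeformer"`; its `fit$history`
#'   records the per-epoch mean training loss.
#' @export
fit_swipeformer <- function(sequences, y, cfg = transformer_config(),
                            target_user_id = NA_character_) {
  stopifnot(inherits(cfg, "transformer_config"))
  Xb <- as_sequence_array(sequences)
  y <- as.integer(y)
  if (length(y) != dim(Xb)[1]) stopf("labels and sequences differ in length")
  if (length(unique(y)) < 2L)
    stopf("training labels contain a single class; one-vs-rest fitting needs both")
  if (dim(Xb)[2] != cfg$sequence_length || dim(Xb)[3] != cfg$channels)
    stopf("sequences are %d x %d but config expects %d x %d",
          dim(Xb)[2], dim(Xb)[3], cfg$sequence_length, cfg$channels)

  # reduced-scale cap: keep every positive, subsample negatives (seeded)
  if (is.finite(cfg$max_train_windows) && dim(Xb)[1] > cfg$max_train_windows) {
    pos <- which(y == 1L); neg <- which(y == 0L)
    n_neg <- max(1L, cfg$max_train_windows - length(pos))
    keep <- with_seed(mix_seed(cfg$seed, 707L),
                      sort(c(pos, sample(neg, min(n_neg, length(neg))))))
    Xb <- Xb[keep, , , drop = FALSE]
    y <- y[keep]
  }

  norm_t <- fit_channel_minmax(Xb)
  Xt <- apply_channel_minmax(norm_t, Xb)
  Fb <- magnitude_spectra(Xb)
  norm_f <- fit_channel_minmax(Fb)
  Xf <- apply_channel_minmax(norm_f, Fb)
  Lf <- dim(Xf)[2]

  It <- conv_index(cfg$sequence_length, cfg$conv_kernel, cfg$conv_stride)
  If <- conv_index(Lf, cfg$conv_kernel, cfg$conv_stride)
  PEt <- positional_encoding(nrow(It), cfg$embedding_dim)
  PEf <- positional_encoding(nrow(If), cfg$embedding_dim)

  n <- dim(Xt)[1]
  history <- numeric(0)
  params <- with_seed(mix_seed(cfg$seed, 808L), swipe_init(cfg, Lf))
  if (cfg$epochs > 0L) {
    state <- adam_init(params)
    for (ep in seq_len(cfg$epochs)) {
      ord <- with_seed(mix_seed(cfg$seed, 909L, ep), sample.int(n))
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- swipe_forward(params, Xt[rows, , , drop = FALSE],
                            Xf[rows, , , drop = FALSE], cfg, It, If, PEt, PEf)
        lb <- bce_with_logits(fw$logits, y[rows])
        grads <- swipe_backward(params, fw, cfg, lb$dlogits)
        upd <- adam_step(params, grads, state, lr = cfg$learning_rate)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lb$loss * length(rows)
      }
      history <- c(history, ep_loss / n)
    }
  }

  fit <- list(params = params, cfg = cfg, norm_t = norm_t, norm_f = norm_f,
              It = It, If = If, PEt = PEt, PEf = PEf, Lf = Lf,
              history = history)
  structure(
    list(model_kind = "swipeformer", target_user_id = target_user_id,
         fit = fit,
         hyperparameters = list(embedding_dim = cfg$embedding_dim,
                                encoder_layers = cfg$encoder_layers,
                                epochs = cfg$epochs),
         cv_table = NULL, grid = NULL, seed = cfg$seed,
         n_train = n, n_features = NA_integer_,
         train_positive_rate = mean(y)),
    class = "fitted_model"
  )
}

.swipe_score <- function(fit, sequences, batch = 256L) {
  Xb <- as_sequence_array(sequences)
  if (dim(Xb)[2] != fit$cfg$sequence_length || dim(Xb)[3] != fit$cfg$channels)
    stopf("sequence shape does not match the fitted transformer")
  Xt <- apply_channel_minmax(fit$norm_t, Xb)
  Xf <- apply_channel_minmax(fit$norm_f, magnitude_spectra(Xb))
  n <- dim(Xt)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    rows <- start:min(start + batch - 1L, n)
    fw <- swipe_forward(fit$params, Xt[rows, , , drop = FALSE],
                        Xf[rows, , , drop = FALSE], fit$cfg,
                        fit$It, fit$If, fit$PEt, fit$PEf)
    out[rows] <- as.numeric(sigmoid(fw$logits))
  }
  out
}
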