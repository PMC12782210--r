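# Minimal neural-network core: dense layers, layer normalization,
# multi-head self-attention, 1-d convolution via im2col, the Adam
# optimizer, and a small feed-forward classifier built from them. All
# gradients are hand-derived and verified against finite differences in the
# test suite. Everything is deterministic given a seed (no threading inside
# R code; BLAS calls are single-threaded under the intended 1-CPU runs).

# ---- parameter-tree helpers -----------------------------------------------

# Apply f elementwise over a nested list of arrays.
ptree_map <- function(p, f) {
  if (is.list(p)) lapply(p, ptree_map, f = f) else f(p)
}

# Apply f over two parallel nested lists of arrays.
ptree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- ptree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

ptree_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, ptree_flatten), use.names = FALSE)
  else as.numeric(p)
}

ptree_unflatten <- function(p, v) {
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- array(v[(i + 1L):(i + n)], dim = dim(x) %||% n)
    i <<- i + n
    out
  }
  rebuild(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot-uniform weight matrix.
glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = ptree_map(params, function(x) x * 0),
       v = ptree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- ptree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- ptree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- ptree_map2(state$m, state$v,
                    function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps))
  params <- ptree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- elementary layers -----------------------------------------------------

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary cross-entropy with logits; returns loss and d(loss)/d(logits).
bce_with_logits <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / length(y), prob = p)
}

# Row-wise softmax.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Layer normalization over rows. Returns output and backward cache.
ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(cache, g, dY) {
  xhat <- cache$xhat; inv <- cache$inv
  d <- ncol(xhat)
  dxhat <- sweep(dY, 2, g, "*")
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dX <- inv * (dxhat - s1 / d - xhat * (s2 / d))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Multi-head self-attention on one sequence X (L x d).
attn_init <- function(d, seed_offset = 0) {
  list(Wq = glorot(d, d), bq = numeric(d),
       Wk = glorot(d, d), bk = numeric(d),
       Wv = glorot(d, d), bv = numeric(d),
       Wo = glorot(d, d), bo = numeric(d))
}

attn_forward <- function(X, p, heads) {
  d <- ncol(X); dh <- d %/% heads
  Q <- sweep(X %*% p$Wq, 2, p$bq, "+")
  K <- sweep(X %*% p$Wk, 2, p$bk, "+")
  V <- sweep(X %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, nrow(X), d)
  A_list <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Z <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(Z)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  Y <- sweep(O %*% p$Wo, 2, p$bo, "+")
  list(Y = Y, cache = list(X = X, Q = Q, K = K, V = V, A = A_list, O = O))
}

attn_backward <- function(cache, p, heads, dY) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V; O <- cache$O
  d <- ncol(X); dh <- d %/% heads
  dWo <- crossprod(O, dY)
  dbo <- colSums(dY)
  dO <- tcrossprod(dY, p$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dZ <- A * (dA - rowSums(dA * A))      # softmax backward, row-wise
    dZ <- dZ / sqrt(dh)
    dQ[, cols] <- dZ %*% K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dZ, Q[, cols, drop = FALSE])
  }
  list(dX = tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# im2col index matrix for a length-L sequence, kernel k, given stride.
conv_index <- function(L, k, stride) {
  Lout <- (L - k) %/% stride + 1L
  if (Lout < 1L) stopf("sequence of length %d too short for kernel %d", L, k)
  outer(seq_len(Lout) * stride - stride, seq_len(k), `+`)  # Lout x k
}

# Unfold one L x C sequence into Lout x (k*C) patches (channel-major blocks).
im2col <- function(X, I) {
  k <- ncol(I); Lout <- nrow(I); C <- ncol(X)
  Xc <- matrix(0, Lout, k * C)
  for (cc in seq_len(C))
    Xc[, (cc - 1L) * k + seq_len(k)] <- matrix(X[as.vector(I), cc], Lout, k)
  Xc
}

# Fixed sinusoidal positional encoding (L x d).
positional_encoding <- function(L, d) {
  pos <- seq_len(L) - 1L
  PE <- matrix(0, L, d)
  for (j in seq_len(d)) {
    freq <- 1 / 10000^((2 * ((j - 1L) %/% 2)) / d)
    PE[, j] <- if (j %% 2 == 1L) sin(pos * freq) else cos(pos * freq)
  }
  PE
}

# ---- small feed-forward classifier (the classical "NN" model) --------------

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers))
    layers[[i]] <- list(W = glorot(sizes[i], sizes[i + 1L]),
                        b = numeric(sizes[i + 1L]))
  layers
}

mlp_forward <- function(layers, X) {
  n <- length(layers)
  acts <- vector("list", n + 1L)
  acts[[1L]] <- X
  for (i in seq_len(n)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < n) relu(Z) else Z   # linear output (logits)
  }
  list(logits = acts[[n + 1L]], acts = acts)
}

mlp_backward <- function(layers, acts, dlogits, l2 = 0) {
  n <- length(layers)
  grads <- vector("list", n)
  dZ <- dlogits
  dA <- NULL
  for (i in rev(seq_len(n))) {
    A <- acts[[i]]
    grads[[i]] <- list(W = crossprod(A, dZ) + l2 * layers[[i]]$W,
                       b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[i]]$W)
    if (i > 1L) dZ <- dA * (acts[[i]] > 0)  # through the ReLU
  }
  list(grads = grads, dX = dA)
}

# Train a binary MLP classifier with Adam + L2 (alpha). Used as the
# feed-forward neural-network model: one hidden layer of 100 rectified
# units by default.
mlp_fit <- function(X, y, hidden = 100L, alpha = 1e-4, epochs = 40L,
                    batch_size = 64L, lr = 1e-3, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  with_seed(mix_seed(seed, 303L), {
    layers <- mlp_init(c(ncol(X), hidden, 1L))
    state <- adam_init(layers)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        fw <- mlp_forward(layers, X[rows, , drop = FALSE])
        lb <- bce_with_logits(fw$logits, y[rows])
        grads <- mlp_backward(layers, fw$acts, lb$dlogits, l2 = alpha / n)$grads
        upd <- adam_step(layers, grads, state, lr = lr)
        layers <- upd$params; state <- upd$state
      }
    }
    list(layers = layers, hidden = hidden, alpha = alpha,
         epochs = epochs, lr = lr, seed = seed)
  })
}

mlp_score <- function(fit, X) {
  as.numeric(sigmoid(mlp_forward(fit$layers, as.matrix(X))$logits))
}
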