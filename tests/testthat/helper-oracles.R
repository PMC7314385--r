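# Independent explicit-loop oracles for the encoder math.  These recompute
# every operation with scalar loops (triple-loop matrix products, per-row
# softmax and normalization written out), so they share no code path with the
# package's vectorized implementation.

matmul_loop <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (t in seq_len(ncol(A))) s <- s + A[i, t] * B[t, j]
      out[i, j] <- s
    }
  }
  out
}

softmax_row_loop <- function(z) {
  m <- max(z)
  e <- exp(z - m)
  e / sum(e)
}

oracle_embed <- function(ids, seg, n, params) {
  d <- ncol(params$tok_emb)
  S <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      S[i, j] <- params$tok_emb[ids[i] + 1L, j] +
        params$seg_emb[seg[i] + 1L, j] + params$pos_emb[i, j]
    }
  }
  S
}

oracle_attention_head <- function(S, Wq, Wk, Wv) {
  n <- nrow(S)
  l <- ncol(Wq)
  Q <- matmul_loop(S, Wq)
  K <- matmul_loop(S, Wk)
  V <- matmul_loop(S, Wv)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    z <- numeric(n)
    for (j in seq_len(n)) {
      s <- 0
      for (t in seq_len(l)) s <- s + Q[i, t] * K[j, t]
      z[j] <- s / sqrt(l)
    }
    A[i, ] <- softmax_row_loop(z)
  }
  matmul_loop(A, V)
}

oracle_layer_norm <- function(X, g, b, eps) {
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    mu <- mean(x)
    v <- mean((x - mu)^2)
    out[i, ] <- (x - mu) / sqrt(v + eps) * g + b
  }
  out
}

oracle_multi_head <- function(S, stack, config) {
  l <- config$l
  C <- matrix(0, nrow(S), config$d)
  for (i in seq_len(config$h)) {
    cols <- ((i - 1L) * l + 1L):(i * l)
    C[, cols] <- oracle_attention_head(S, stack$Wq[, cols, drop = FALSE],
                                       stack$Wk[, cols, drop = FALSE],
                                       stack$Wv[, cols, drop = FALSE])
  }
  O <- if (config$variant == "standard") matmul_loop(C, stack$Wo) else C
  oracle_layer_norm(S + O, stack$ln1_g, stack$ln1_b, config$ln_eps)
}

oracle_ffn <- function(M, stack, config) {
  H <- matmul_loop(M, stack$W1)
  for (i in seq_len(nrow(H))) H[i, ] <- H[i, ] + stack$b1
  H[H < 0] <- 0
  F_out <- matmul_loop(H, stack$W2)
  for (i in seq_len(nrow(F_out))) F_out[i, ] <- F_out[i, ] + stack$b2
  if (config$variant == "standard") {
    oracle_layer_norm(M + F_out, stack$ln2_g, stack$ln2_b, config$ln_eps)
  } else {
    F_out
  }
}

oracle_forward <- function(seq, params, config) {
  n <- seq$n_valid
  S <- oracle_embed(seq$ids[seq_len(n)], seq$segment_ids[seq_len(n)], n,
                    params)
  for (ki in seq_len(config$k)) {
    S <- oracle_ffn(oracle_multi_head(S, params$stacks[[ki]], config),
                    params$stacks[[ki]], config)
  }
  scores <- numeric(config$n_classes)
  for (c in seq_len(config$n_classes)) {
    scores[c] <- sum(params$Wpred[c, ] * S[1L, ])
  }
  scores
}
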