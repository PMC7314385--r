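test_that("embedding rows are the three-way table sums", {
  cfg <- model_config(k = 0, h = 2, d = 6, n_max = 8, vocab_size = 10,
                      classes = letters[1:6])
  p <- init_params(cfg, seed = 1)
  s <- random_token_sequence(cfg, n_valid = 4, seed = 2)
  expect_equal(embed_tokens(s, p),
               oracle_embed(s$ids[1:4], s$segment_ids[1:4], 4, p))
  # zero tables -> zero matrix
  p0 <- p
  p0$tok_emb[] <- 0; p0$seg_emb[] <- 0; p0$pos_emb[] <- 0
  expect_equal(embed_tokens(s, p0), matrix(0, 4, 6))
  # one-hot token table with zero others picks out embedding rows
  p1 <- p0
  p1$tok_emb <- diag(10)[, 1:6]
  S <- embed_tokens(s, p1)
  for (i in 1:4) expect_equal(S[i, ], p1$tok_emb[s$ids[i] + 1, ])
  # out-of-range ids abort
  s_bad <- s
  s_bad$ids[2] <- 99L
  expect_error(embed_tokens(s_bad, p), "out of range")
})

test_that("attention head matches the scalar loop oracle and its limits", {
  set.seed(11)
  S <- matrix(rnorm(3 * 4), 3, 4)
  Wq <- matrix(rnorm(8), 4, 2)
  Wk <- matrix(rnorm(8), 4, 2)
  Wv <- matrix(rnorm(8), 4, 2)
  expect_equal(attention_head(S, Wq, Wk, Wv),
               oracle_attention_head(S, Wq, Wk, Wv), tolerance = 1e-10)
  # n = 1: softmax over one element, output equals the single value row
  S1 <- S[1, , drop = FALSE]
  expect_equal(attention_head(S1, Wq, Wk, Wv), S1 %*% Wv)
  # zero query -> uniform attention -> every row is the value column mean
  O <- attention_head(S, 0 * Wq, Wk, Wv)
  V <- S %*% Wv
  for (i in 1:3) expect_equal(O[i, ], colMeans(V))
  expect_error(attention_head(S * NA, Wq, Wk, Wv), "non-finite")
})

test_that("multi-head concatenation, projection and normalization match oracles", {
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 10)
  p <- init_params(cfg, seed = 4)
  set.seed(5)
  S <- matrix(rnorm(3 * 4), 3, 4)
  st <- p$stacks[[1]]
  expect_equal(multi_head(S, st, cfg), oracle_multi_head(S, st, cfg),
               tolerance = 1e-10)
  # rows are standardized before gain/bias: mean 0, variance ~ 1
  st_id <- st
  st_id$ln1_g <- rep(1, 4); st_id$ln1_b <- rep(0, 4)
  M <- multi_head(S, st_id, cfg)
  expect_equal(rowMeans(M), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(M, 1, function(r) mean(r^2)), rep(1, 3),
               tolerance = 1e-4)
  # h = 1 reduces to a single projected head through residual + LN
  cfg1 <- model_config(k = 1, h = 1, d = 4, n_max = 8, vocab_size = 10)
  O1 <- attention_head(S, st$Wq, st$Wk, st$Wv)
  manual <- .layer_norm_test(S + O1 %*% st$Wo, st$ln1_g, st$ln1_b, cfg1$ln_eps)
  expect_equal(multi_head(S, st, cfg1), manual, tolerance = 1e-10)
})

test_that("the feed-forward sub-layer is position-wise and matches its oracle", {
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 10)
  p <- init_params(cfg, seed = 6)
  st <- p$stacks[[1]]
  set.seed(7)
  M <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(feed_forward(M, st, cfg), oracle_ffn(M, st, cfg),
               tolerance = 1e-10)
  # zero weights -> LN(M)
  st0 <- st
  st0$W1[] <- 0; st0$W2[] <- 0; st0$b1[] <- 0; st0$b2[] <- 0
  expect_equal(feed_forward(M, st0, cfg),
               oracle_layer_norm(M, st$ln2_g, st$ln2_b, cfg$ln_eps),
               tolerance = 1e-10)
  # permuting input rows permutes output rows identically
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(feed_forward(M[perm, ], st, cfg),
               feed_forward(M, st, cfg)[perm, ], tolerance = 1e-12)
  # single position equals the scalar computation
  expect_equal(feed_forward(M[2, , drop = FALSE], st, cfg),
               oracle_ffn(M[2, , drop = FALSE], st, cfg), tolerance = 1e-10)
})

test_that("the full forward pass matches the composed loop oracle", {
  for (case in list(list(k = 2, h = 2, d = 8, n = 5),
                    list(k = 1, h = 1, d = 4, n = 3),
                    list(k = 2, h = 1, d = 6, n = 6))) {
    cfg <- model_config(k = case$k, h = case$h, d = case$d, n_max = 8,
                        vocab_size = 12)
    p <- init_params(cfg, seed = case$n, init_sd = 0.5)
    s <- random_token_sequence(cfg, n_valid = case$n, seed = case$k + 10)
    fw <- transformer_forward(s, p, cfg)
    expect_equal(unname(fw$scores), oracle_forward(s, p, cfg),
                 tolerance = 1e-8)
    expect_equal(sum(fw$probs), 1, tolerance = 1e-12)
  }
})

test_that("with zero stacks and an identity slice the scores are the CLS embedding", {
  cfg <- model_config(k = 0, h = 1, d = 4, n_max = 8, vocab_size = 10,
                      classes = letters[1:4])
  p <- init_params(cfg, seed = 8)
  p$Wpred <- diag(4)
  s <- random_token_sequence(cfg, n_valid = 3, seed = 9)
  fw <- transformer_forward(s, p, cfg)
  expect_equal(unname(fw$scores), embed_tokens(s, p)[1, ])
})

test_that("appending pad tokens never changes the CLS class scores", {
  cfg <- model_config(k = 2, h = 2, d = 8, n_max = 16, vocab_size = 12)
  p <- init_params(cfg, seed = 10)
  s_short <- random_token_sequence(cfg, n_valid = 5, max_len = 5, seed = 11)
  s_padded <- s_short
  s_padded$tokens <- c(s_short$tokens, rep("[PAD]", 7))
  s_padded$ids <- c(s_short$ids, rep(0L, 7))
  s_padded$positions <- 0:11
  s_padded$segment_ids <- rep(0L, 12)
  s_padded$n <- 12L
  expect_equal(transformer_forward(s_padded, p, cfg)$scores,
               transformer_forward(s_short, p, cfg)$scores)
})

test_that("attention rows are probability vectors at every head and stack", {
  cfg <- model_config(k = 2, h = 2, d = 8, n_max = 8, vocab_size = 12)
  p <- init_params(cfg, seed = 12, init_sd = 0.3)
  s <- random_token_sequence(cfg, n_valid = 6, seed = 13)
  for (ki in 1:2) {
    A <- export_attention(s, p, cfg, ki)
    expect_equal(dim(A), c(2, 6, 6))
    expect_true(all(A >= 0))
    expect_equal(unname(apply(A, c(1, 2), sum)), matrix(1, 2, 6),
                 tolerance = 1e-6)
  }
  expect_error(export_attention(s, p, cfg, 3), "out of range")
  # single-token sequence: all attention weight on the one position
  s1 <- random_token_sequence(cfg, n_valid = 2, seed = 14)
  A1 <- export_attention(s1, p, cfg, 1)
  expect_equal(unname(apply(A1, c(1, 2), sum)), matrix(1, 2, 2),
               tolerance = 1e-9)
  # exported weights agree with attention_head's own matrices at stack 1
  S0 <- embed_tokens(s, p)
  st <- p$stacks[[1]]
  det <- attention_head(S0, st$Wq[, 1:4], st$Wk[, 1:4], st$Wv[, 1:4],
                        return_details = TRUE)
  expect_equal(unname(export_attention(s, p, cfg, 1)[1, , ]), det$weights,
               tolerance = 1e-12)
})

test_that("sqrt(l) scaling keeps attention-logit variance invariant to l", {
  set.seed(15)
  # with Q = K = S the diagonal logits are chi-square distributed and grow
  # with l, so the invariance statement concerns the off-diagonal entries
  vars <- vapply(c(2, 8, 32), function(l) {
    n <- 40
    S <- matrix(rnorm(n * l), n, l)
    det <- attention_head(S, diag(l), diag(l), diag(l),
                          return_details = TRUE)
    Z <- det$logits
    stats::var(Z[row(Z) != col(Z)])
  }, numeric(1))
  expect_true(all(abs(vars - 1) < 0.35))
})

test_that("the literal variant drops projection and FFN residual", {
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 10,
                      variant = "literal")
  p <- init_params(cfg, seed = 16)
  st <- p$stacks[[1]]
  set.seed(17)
  M <- matrix(rnorm(3 * 4), 3, 4)
  raw <- pmax(sweep(M %*% st$W1, 2, st$b1, `+`), 0) %*% st$W2
  raw <- sweep(raw, 2, st$b2, `+`)
  expect_equal(feed_forward(M, st, cfg), raw, tolerance = 1e-12)
  s <- random_token_sequence(cfg, n_valid = 4, seed = 18)
  expect_equal(unname(transformer_forward(s, p, cfg)$scores),
               oracle_forward(s, p, cfg), tolerance = 1e-8)
  cfg_std <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 10)
  expect_false(isTRUE(all.equal(transformer_forward(s, p, cfg)$scores,
                                transformer_forward(s, p, cfg_std)$scores)))
})

test_that("weight archives round-trip, validate shapes and report extras", {
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 10)
  p <- init_params(cfg, seed = 19)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_model_params(p, f)
  p2 <- load_pretrained(f, cfg)
  expect_equal(p2, p)
  s <- random_token_sequence(cfg, n_valid = 4, seed = 20)
  expect_identical(transformer_forward(s, p2, cfg)$scores,
                   transformer_forward(s, p2, cfg)$scores)  # deterministic
  # truncated archive: error names the missing tensors
  flat <- readRDS(f)
  flat$`stack01.Wq` <- NULL
  saveRDS(flat, f)
  expect_error(load_pretrained(f, cfg), "stack01.Wq")
  # shape mismatch is named
  flat$`stack01.Wq` <- matrix(0, 2, 2)
  saveRDS(flat, f)
  expect_error(load_pretrained(f, cfg), "shape mismatch.*stack01.Wq")
  # external names are ingested through a mapping; unmapped extras reported
  flat <- .flatten_params_test(p)
  names(flat)[names(flat) == "stack01.Wq"] <- "encoder.layer.0.query"
  flat$leftover <- 1
  saveRDS(flat, f)
  expect_message(
    p3 <- load_pretrained(f, cfg,
                          mapping = c("encoder.layer.0.query" = "stack01.Wq")),
    "leftover")
  expect_equal(p3$stacks[[1]]$Wq, p$stacks[[1]]$Wq)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 8, vocab_size = 8,
                      dropout = 0)
  p <- init_params(cfg, seed = 21, init_sd = 0.3)
  s <- random_token_sequence(cfg, n_valid = 4, seed = 22)
  y <- 2L
  fw <- .forward_cached_test(s, p, cfg)
  dsc <- fw$probs
  dsc[y] <- dsc[y] - 1
  g <- .backward_cached_test(fw, dsc, p, cfg)
  flat <- .flatten_params_test(p)
  loss_at <- function(flat) {
    f <- .forward_cached_test(s, .unflatten_params_test(flat, cfg), cfg)
    -log(f$probs[y])
  }
  set.seed(23)
  h <- 1e-5
  for (nm in names(g)) {
    for (t in 1:2) {
      i <- sample(length(flat[[nm]]), 1)
      fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + h
      fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - h
      num <- (loss_at(fp) - loss_at(fm)) / (2 * h)
      rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-3, label = sprintf("grad %s[%d] rel err", nm, i))
    }
  }
})
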