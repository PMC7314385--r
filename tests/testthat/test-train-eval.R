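test_that("precision/recall/F1 follow the contingency arithmetic", {
  # all correct -> 100 everywhere
  m <- evaluate_predictions(c("CID", "negative", "CID"),
                            c("CID", "negative", "CID"))
  expect_equal(m$per_class$precision, 100)
  expect_equal(m$per_class$recall, 100)
  expect_equal(m$per_class$f1, 100)
  # complement predictions on a balanced binary set -> all zero
  m0 <- evaluate_predictions(c("negative", "CID"), c("CID", "negative"))
  expect_equal(m0$per_class$f1[m0$per_class$class == "CID"], 0)
  # TP=3 FP=1 FN=2 -> P 75, R 60, F1 66.7
  gold <- c(rep("CID", 5), rep("negative", 5))
  pred <- c("CID", "CID", "CID", "negative", "negative",
            "CID", rep("negative", 4))
  m1 <- evaluate_predictions(pred, gold)
  expect_equal(m1$per_class$precision, 75)
  expect_equal(m1$per_class$recall, 60)
  expect_equal(m1$per_class$f1, 200 / 3, tolerance = 1e-12)
  # micro over a single evaluated class equals that class's F1
  expect_equal(m1$micro$f1, m1$per_class$f1)
})

test_that("metrics agree with a brute-force confusion-matrix oracle", {
  set.seed(31)
  classes <- c("negative", "int", "advice", "effect")
  for (rep in 1:10) {
    n <- 60
    gold <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- evaluate_predictions(pred, gold, classes = classes[-1])
    tp_all <- fp_all <- fn_all <- 0
    for (cl in classes[-1]) {
      tp <- 0; fp <- 0; fn <- 0
      for (i in seq_len(n)) {
        if (pred[i] == cl && gold[i] == cl) tp <- tp + 1
        if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
        if (pred[i] != cl && gold[i] == cl) fn <- fn + 1
      }
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$tp, tp)
      expect_equal(row$fp, fp)
      expect_equal(row$fn, fn)
      p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
      r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
      expect_equal(row$precision, p)
      expect_equal(row$recall, r)
      expect_equal(row$f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
      tp_all <- tp_all + tp; fp_all <- fp_all + fp; fn_all <- fn_all + fn
    }
    pm <- if (tp_all + fp_all > 0) 100 * tp_all / (tp_all + fp_all) else 0
    rm <- if (tp_all + fn_all > 0) 100 * tp_all / (tp_all + fn_all) else 0
    expect_equal(m$micro$precision, pm)
    expect_equal(m$micro$recall, rm)
  }
})

test_that("run averaging is the arithmetic mean of every field", {
  mk <- function(f1s) {
    gold <- c("CID", "CID", "negative")
    m <- evaluate_predictions(gold, gold)
    m$per_class$f1 <- f1s
    m$micro$f1 <- f1s
    m
  }
  expect_equal(average_runs(list(mk(60)))$micro$f1, 60)
  expect_equal(average_runs(list(mk(60), mk(70)))$micro$f1, 65)
  set.seed(32)
  vals <- runif(5, 0, 100)
  avg <- average_runs(lapply(vals, mk))
  oracle <- 0
  for (v in vals) oracle <- oracle + v / 5
  expect_equal(avg$micro$f1, oracle)
  bad <- evaluate_predictions(c("int"), c("int"))
  expect_error(average_runs(list(mk(50), bad)), "inconsistent class sets")
})

test_that("length bins partition instances and match a filtering oracle", {
  docs <- generate_corpus(synthetic_config(n_docs = 12L, seed = 41L))
  inst <- suppressWarnings(build_instances(docs))
  gold <- vapply(inst, `[[`, "", "label")
  set.seed(42)
  pred <- sample(c("CID", "negative"), length(inst), replace = TRUE)
  rep_bins <- length_binned_eval(inst, pred)
  expect_equal(sum(rep_bins$n), length(inst))
  expect_equal(sum(rep_bins$positive + rep_bins$negative), length(inst))
  lens <- vapply(inst, function(x) {
    length(gregexpr("\\S+", x$text)[[1]])
  }, integer(1))
  # an instance of length 120 falls in the 101-150 bin
  expect_identical(as.character(cut(120, c(0, seq(50, 400, 50), Inf),
                                    labels = rep_bins$interval)), "101-150")
  for (b in seq_len(nrow(rep_bins))) {
    lo <- (b - 1) * 50
    hi <- if (b == nrow(rep_bins)) Inf else b * 50
    in_b <- lens > lo & lens <= hi
    expect_equal(rep_bins$positive[b], sum(gold[in_b] != "negative"))
    expect_equal(rep_bins$n[b], sum(in_b))
    if (any(in_b)) {
      sub <- evaluate_predictions(pred[in_b], gold[in_b])
      expect_equal(rep_bins$f1[b], sub$micro$f1)
    }
  }
})

test_that("zero epochs leave the parameters untouched", {
  vocab <- toy_vocab(c("a", "b"))
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 6, vocab_size = vocab$size)
  p <- init_params(cfg, seed = 51)
  s <- tokenize_sequence("a b", vocab, 6)
  s$label <- "CID"
  fit <- train_model(p, cfg, list(s), train_config(epochs = 0))
  expect_identical(fit$params, p)
  expect_length(fit$loss, 0)
  expect_error(train_model(p, cfg, list(), train_config()), "empty training")
  s$label <- "bogus"
  expect_error(train_model(p, cfg, list(s), train_config()), "unknown label")
})

test_that("full-batch loss on a repeated batch decreases over 50 steps", {
  vocab <- toy_vocab(c("alpha", "beta", "gamma", "delta"))
  cfg <- model_config(k = 1, h = 2, d = 8, n_max = 8,
                      vocab_size = vocab$size, dropout = 0)
  texts <- c("alpha beta", "beta gamma delta", "gamma alpha",
             "delta delta beta", "alpha gamma", "beta beta")
  labels <- rep(c("CID", "negative"), 3)
  seqs <- Map(function(t, l) {
    s <- tokenize_sequence(t, vocab, 8)
    s$label <- l
    s
  }, texts, labels)
  tcfg <- train_config(epochs = 50, batch_size = length(seqs), lr = 1e-3,
                       warmup_frac = 0, lr_decay = FALSE, seed = 52)
  fit <- train_model(init_params(cfg, seed = 52, init_sd = 0.2), cfg,
                     unname(seqs), tcfg)
  expect_length(fit$loss, 50)
  expect_lt(fit$loss[50], fit$loss[1])
  # optimization sanity: the full-batch loss never increases step to step
  expect_true(all(diff(fit$loss) <= 0))
})

test_that("training is deterministic given the seed", {
  vocab <- toy_vocab(c("a", "b", "c"))
  cfg <- model_config(k = 1, h = 2, d = 4, n_max = 6,
                      vocab_size = vocab$size)
  seqs <- lapply(c("a b", "b c", "c a b"), function(t) {
    s <- tokenize_sequence(t, vocab, 6)
    s$label <- "CID"
    s
  })
  tcfg <- train_config(epochs = 2, batch_size = 2, lr = 1e-3, seed = 53)
  f1 <- train_model(init_params(cfg, seed = 53), cfg, seqs, tcfg)
  f2 <- train_model(init_params(cfg, seed = 53), cfg, seqs, tcfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$params, f2$params)
})

test_that("attention reports expose per-head probability rows for queried tokens", {
  vocab <- toy_vocab(c("chemical", "disease", "induced"))
  cfg <- model_config(k = 2, h = 2, d = 8, n_max = 8,
                      vocab_size = vocab$size)
  p <- init_params(cfg, seed = 54)
  s <- tokenize_sequence("chemical induced disease", vocab, 8)
  rep1 <- attention_report(p, cfg, s, c("[CLS]", "chemical", "disease"))
  for (q in names(rep1$reports)) {
    for (occ in rep1$reports[[q]]) {
      expect_equal(unname(rowSums(occ$weights)), rep(1, cfg$h),
                   tolerance = 1e-6)
    }
  }
  # querying [CLS] returns row 1 of the exported attention matrices
  A <- export_attention(s, p, cfg, 2)
  expect_equal(unname(rep1$reports[["[CLS]"]][[1]]$weights),
               unname(A[, 1, ]))
  expect_identical(rep1$reports[["[CLS]"]][[1]]$position, 1L)
  # deterministic across repeated calls
  rep2 <- attention_report(p, cfg, s, "[CLS]")
  expect_identical(rep1$reports[["[CLS]"]], rep2$reports[["[CLS]"]])
  expect_error(attention_report(p, cfg, s, "absent"), "absent")
})

test_that("replacement pretreatment is non-inferior to addition on nonce entities", {
  cfg <- synthetic_config(n_docs = 260L, chemicals_per_doc = c(1L, 1L),
                          diseases_per_doc = c(1L, 1L),
                          nonce_entities = TRUE, seed = 60L)
  inst <- suppressWarnings(build_instances(generate_corpus(cfg)))
  train_idx <- 1:200
  eval_idx <- 201:260
  f1_for <- function(mode) {
    pre <- pretreat_instances(inst, mode)
    vocab <- build_vocab(pre)
    seqs <- tokenize_instances(pre[train_idx], vocab, 128)
    eseqs <- tokenize_instances(pre[eval_idx], vocab, 128)
    mcfg <- model_config(k = 2, h = 2, d = 32, n_max = 128,
                         vocab_size = vocab$size, dropout = 0)
    tcfg <- train_config(epochs = 3, batch_size = 1, lr = 1e-3, seed = 42)
    fit <- train_model(init_params(mcfg, seed = 42, init_sd = 0.1),
                       mcfg, seqs, tcfg)
    pred <- predict_model(fit$params, mcfg, eseqs)
    evaluate_predictions(pred$labels,
                         vapply(eseqs, `[[`, "", "label"))$micro$f1
  }
  f1_rep <- f1_for("replacement")
  f1_add <- f1_for("addition")
  expect_gte(f1_rep, f1_add - 2)
})
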