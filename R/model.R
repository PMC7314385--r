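# Multi-head self-attention encoder and relation classifier.
#
# The encoder is a stack of k transformer blocks over an input matrix
# S0 = token + segment + position embeddings (n x d).  Each block applies
# h-head scaled dot-product attention
#     A   = row_softmax( (S Wq)(S Wk)^T / sqrt(l) ),   l = d / h,
#     O_h = A (S Wv),
# concatenates the head outputs, and (in the standard variant) projects them
# with a d x d output matrix, followed by residual connection + layer
# normalization and a position-wise two-layer ReLU feed-forward network with
# its own residual + layer normalization.  The "literal" variant omits the
# output projection and the FFN residual/normalization (the minimal published
# block; see the methods vignette).  Class scores are a linear map of the
# final-stack [CLS] row (position 1).  All math is plain CPU matrix algebra;
# a matching exact backward pass lives in train.R.

#' Encoder configuration
#'
#' @param k Number of transformer stacks.
#' @param h Number of attention heads.
#' @param d Model/embedding dimension; must be divisible by `h`.  The
#'   per-head dimension is `l = d/h`.
#' @param m Inner feed-forward dimension (default `4 * d`).
#' @param n_max Maximum sequence length (positions `0..n_max-1`).
#' @param vocab_size Vocabulary size.
#' @param classes Character vector of class labels; its length sets the
#'   number of output classes.
#' @param ln_eps Layer-normalization epsilon.
#' @param dropout Dropout rate applied to sub-layer outputs during training.
#' @param variant `"standard"` (output projection + FFN residual/LN) or
#'   `"literal"` (minimal block).
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(k, h, d, m = 4L * d, n_max = 128L, vocab_size,
                         classes = c("negative", "CID"), ln_eps = 1e-12,
                         dropout = 0.1, variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  k <- as.integer(k); h <- as.integer(h); d <- as.integer(d)
  if (d %% max(h, 1L) != 0L) stop("d must be divisible by h")
  if (any(c(h, d, m, n_max, vocab_size) <= 0L) || k < 0L) {
    stop("all dimensions must be positive (k may be 0)")
  }
  structure(
    list(k = k, h = h, d = d, l = d %/% h, m = as.integer(m),
         n_max = as.integer(n_max), vocab_size = as.integer(vocab_size),
         n_classes = length(classes), classes = as.character(classes),
         ln_eps = ln_eps, dropout = dropout, variant = variant),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config: k=%d stacks, h=%d heads, d=%d (l=%d), m=%d, n_max=%d, vocab=%d, classes=%s, variant=%s>\n",
    x$k, x$h, x$d, x$l, x$m, x$n_max, x$vocab_size,
    paste(x$classes, collapse = "/"), x$variant))
  invisible(x)
}

.sinusoidal_positions <- function(n_max, d, scale) {
  pos <- matrix(0, n_max, d)
  half <- d %/% 2L
  for (j in seq_len(half)) {
    freq <- 1 / 10000^((2 * (j - 1)) / d)
    pos[, 2L * j - 1L] <- sin((seq_len(n_max) - 1L) * freq)
    pos[, 2L * j] <- cos((seq_len(n_max) - 1L) * freq)
  }
  pos * scale
}

#' Initialize model parameters
#'
#' Weights are drawn from N(0, `init_sd`^2); layer-norm gains start at 1 and
#' biases at 0.  Position embeddings start from scaled sinusoids by default
#' (they remain trainable): the fixed phase structure makes relative-offset
#' attention linearly representable from the first step, which markedly
#' speeds up from-scratch training of small models; `pos_init = "random"`
#' matches the other tables.
#'
#' @param config A `"model_config"`.
#' @param seed RNG seed.
#' @param init_sd Initialization standard deviation (also the sinusoid
#'   amplitude, keeping positions on the token-embedding scale).
#' @param pos_init `"sinusoidal"` or `"random"` position-table start.
#' @return A nested parameter list (`tok_emb`, `seg_emb`, `pos_emb`, one list
#'   per stack with `Wq`, `Wk`, `Wv`, `Wo`, `ln1_g`, `ln1_b`, `W1`, `b1`,
#'   `W2`, `b2`, `ln2_g`, `ln2_b`, and the classifier weight `Wpred`).
#' @export
init_params <- function(config, seed = 1L, init_sd = 0.02,
                        pos_init = c("sinusoidal", "random")) {
  pos_init <- match.arg(pos_init)
  set.seed(seed)
  d <- config$d; m <- config$m
  mat <- function(a, b) matrix(stats::rnorm(a * b, 0, init_sd), a, b)
  stacks <- lapply(seq_len(config$k), function(i) {
    list(Wq = mat(d, d), Wk = mat(d, d), Wv = mat(d, d), Wo = mat(d, d),
         ln1_g = rep(1, d), ln1_b = rep(0, d),
         W1 = mat(d, m), b1 = rep(0, m), W2 = mat(m, d), b2 = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d))
  })
  pos_emb <- if (pos_init == "sinusoidal" && config$d %% 2L == 0L) {
    .sinusoidal_positions(config$n_max, d, init_sd)
  } else {
    mat(config$n_max, d)
  }
  list(tok_emb = mat(config$vocab_size, d), seg_emb = mat(2L, d),
       pos_emb = pos_emb, stacks = stacks,
       Wpred = mat(config$n_classes, d))
}

.row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

.layer_norm <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  Xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(Xc * Xc) + eps)
  xhat <- Xc * inv_sd
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`),
       xhat = xhat, inv_sd = inv_sd)
}

#' Embed a token sequence
#'
#' Row i of the result is the element-wise sum of the token, segment and
#' position embeddings: `tok_emb[id_i] + seg_emb[seg_i] + pos_emb[i]`.
#' Only the valid (non-pad) positions are embedded; padding never enters the
#' encoder, which is equivalent to masking padded keys out of every softmax.
#'
#' @param seq A `"token_sequence"`.
#' @param params Parameter list from [init_params()].
#' @return Matrix `S0` of shape `n_valid x d`.
#' @export
embed_tokens <- function(seq, params) {
  n <- seq$n_valid
  ids <- seq$ids[seq_len(n)]
  if (anyNA(ids) || any(ids < 0L) || any(ids >= nrow(params$tok_emb))) {
    stop("token id out of range for the embedding table")
  }
  if (n > nrow(params$pos_emb)) stop("sequence longer than the position table")
  params$tok_emb[ids + 1L, , drop = FALSE] +
    params$seg_emb[seq$segment_ids[seq_len(n)] + 1L, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE]
}

#' Single scaled dot-product attention head
#'
#' `A = row_softmax((S Wq)(S Wk)^T / sqrt(l))`; the head output is `A (S Wv)`.
#' The scale is the square root of the per-head dimension `l = ncol(Wq)`.
#'
#' @param S Input matrix (`n x d`), finite values required.
#' @param Wq,Wk,Wv Projection matrices (`d x l`).
#' @param return_details Also return the attention weights and raw logits.
#' @return The `n x l` head output, or (with details) a list with `output`,
#'   `weights` and `logits`.
#' @export
attention_head <- function(S, Wq, Wk, Wv, return_details = FALSE) {
  if (!all(is.finite(S))) stop("non-finite values in attention input")
  l <- ncol(Wq)
  Z <- tcrossprod(S %*% Wq, S %*% Wk) / sqrt(l)
  A <- .row_softmax(Z)
  O <- A %*% (S %*% Wv)
  if (return_details) list(output = O, weights = A, logits = Z) else O
}

#' Multi-head attention sub-layer
#'
#' Runs all `h` heads, concatenates their outputs along the feature axis,
#' applies the output projection (standard variant), adds the residual and
#' layer-normalizes per row: `M = LN(S + O)`.
#'
#' @param S Input matrix (`n x d`).
#' @param stack One element of `params$stacks`.
#' @param config A `"model_config"`.
#' @param return_attention Attach the `h x n x n` attention array as
#'   attribute `"attention"`.
#' @return The `n x d` sub-layer output `M`.
#' @export
multi_head <- function(S, stack, config, return_attention = FALSE) {
  n <- nrow(S)
  h <- config$h
  l <- config$l
  C <- matrix(0, n, config$d)
  attn <- if (return_attention) array(0, c(h, n, n)) else NULL
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * l + 1L):(i * l)
    res <- attention_head(S, stack$Wq[, cols, drop = FALSE],
                          stack$Wk[, cols, drop = FALSE],
                          stack$Wv[, cols, drop = FALSE],
                          return_details = TRUE)
    C[, cols] <- res$output
    if (return_attention) attn[i, , ] <- res$weights
  }
  O <- if (config$variant == "standard") C %*% stack$Wo else C
  M <- .layer_norm(S + O, stack$ln1_g, stack$ln1_b, config$ln_eps)$y
  if (return_attention) attr(M, "attention") <- attn
  M
}

#' Position-wise feed-forward sub-layer
#'
#' Two linear layers with ReLU: `F = ReLU(M W1 + b1) W2 + b2`, applied
#' identically at every position; in the standard variant the block output is
#' `LN(M + F)`, in the literal variant it is `F` itself.
#'
#' @param M Input matrix (`n x d`).
#' @param stack One element of `params$stacks`.
#' @param config A `"model_config"`.
#' @return The `n x d` block output.
#' @export
feed_forward <- function(M, stack, config) {
  H <- sweep(M %*% stack$W1, 2L, stack$b1, `+`)
  F_out <- sweep(pmax(H, 0) %*% stack$W2, 2L, stack$b2, `+`)
  if (config$variant == "standard") {
    .layer_norm(M + F_out, stack$ln2_g, stack$ln2_b, config$ln_eps)$y
  } else {
    F_out
  }
}

#' Full encoder forward pass
#'
#' `S0` is the embedding sum; each stack applies multi-head attention then
#' the feed-forward sub-layer; class scores are `c = Wpred s1` where `s1` is
#' the final-stack output row of the `[CLS]` token (position 1), and class
#' probabilities are `softmax(c)`.
#'
#' @param seq A `"token_sequence"`.
#' @param params Parameter list (structure of [init_params()]).
#' @param config A `"model_config"` consistent with `params`.
#' @param return_states Also return the list of per-stack state matrices.
#' @param return_attention Also return per-stack `h x n x n` attention
#'   arrays.
#' @return List with `scores` (named numeric, length `n_classes`), `probs`
#'   (softmax of scores), `label` (argmax class) and optionally `states` and
#'   `attention`.
#' @export
transformer_forward <- function(seq, params, config, return_states = FALSE,
                                return_attention = FALSE) {
  if (length(params$stacks) != config$k) {
    stop("config/params mismatch: ", length(params$stacks),
         " stacks in params, k = ", config$k)
  }
  S <- embed_tokens(seq, params)
  states <- if (return_states) list(S) else NULL
  attns <- if (return_attention) vector("list", config$k) else NULL
  for (ki in seq_len(config$k)) {
    M <- multi_head(S, params$stacks[[ki]], config,
                    return_attention = return_attention)
    if (return_attention) {
      attns[[ki]] <- attr(M, "attention")
      attr(M, "attention") <- NULL
    }
    S <- feed_forward(M, params$stacks[[ki]], config)
    if (return_states) states[[ki + 1L]] <- S
  }
  scores <- drop(params$Wpred %*% S[1L, ])
  names(scores) <- config$classes
  e <- exp(scores - max(scores))
  probs <- e / sum(e)
  out <- list(scores = scores, probs = probs,
              label = config$classes[which.max(scores)])
  if (return_states) out$states <- states
  if (return_attention) out$attention <- attns
  out
}

#' Export attention matrices of one stack
#'
#' Returns the row-softmax attention matrices of every head at the given
#' stack; rows over the valid (non-pad) positions sum to 1.
#'
#' @param seq A `"token_sequence"`.
#' @param params,config Model parameters and configuration.
#' @param stack_index 1-based stack index (defaults to the final stack).
#' @return Array of shape `h x n_valid x n_valid`; token strings are attached
#'   as dimnames on the query/key axes.
#' @export
export_attention <- function(seq, params, config, stack_index = config$k) {
  if (stack_index < 1L || stack_index > config$k) {
    stop("stack index out of range: ", stack_index)
  }
  fw <- transformer_forward(seq, params, config, return_attention = TRUE)
  A <- fw$attention[[stack_index]]
  toks <- seq$tokens[seq_len(seq$n_valid)]
  dimnames(A) <- list(paste0("head", seq_len(config$h)), toks, toks)
  A
}

## ---- weight archive -------------------------------------------------------

# Flat name schema: tok_emb, seg_emb, pos_emb, stack<ii>.<tensor> with
# ii zero-padded (stack01.Wq, ...), Wpred.  External checkpoints (e.g. a
# converted BERT-style model) are ingested by supplying `mapping` from the
# archive's tensor names to this schema; converter notes live in the README.

.param_shapes <- function(config) {
  d <- config$d; m <- config$m
  shapes <- list(tok_emb = c(config$vocab_size, d), seg_emb = c(2L, d),
                 pos_emb = c(config$n_max, d))
  per_stack <- list(Wq = c(d, d), Wk = c(d, d), Wv = c(d, d), Wo = c(d, d),
                    ln1_g = d, ln1_b = d, W1 = c(d, m), b1 = m,
                    W2 = c(m, d), b2 = d, ln2_g = d, ln2_b = d)
  for (ki in seq_len(config$k)) {
    for (nm in names(per_stack)) {
      shapes[[sprintf("stack%02d.%s", ki, nm)]] <- per_stack[[nm]]
    }
  }
  shapes$Wpred <- c(config$n_classes, d)
  shapes
}

.flatten_params <- function(params) {
  flat <- list(tok_emb = params$tok_emb, seg_emb = params$seg_emb,
               pos_emb = params$pos_emb)
  for (ki in seq_along(params$stacks)) {
    for (nm in names(params$stacks[[ki]])) {
      flat[[sprintf("stack%02d.%s", ki, nm)]] <- params$stacks[[ki]][[nm]]
    }
  }
  flat$Wpred <- params$Wpred
  flat
}

.unflatten_params <- function(flat, config) {
  stacks <- lapply(seq_len(config$k), function(ki) {
    nms <- c("Wq", "Wk", "Wv", "Wo", "ln1_g", "ln1_b", "W1", "b1", "W2", "b2",
             "ln2_g", "ln2_b")
    stats::setNames(lapply(nms, function(nm) {
      flat[[sprintf("stack%02d.%s", ki, nm)]]
    }), nms)
  })
  list(tok_emb = flat$tok_emb, seg_emb = flat$seg_emb,
       pos_emb = flat$pos_emb, stacks = stacks, Wpred = flat$Wpred)
}

.shape_of <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' Save model parameters as a flat named-tensor archive
#'
#' @param params Parameter list.
#' @param path Output file (RDS container of a flat named list; name schema
#'   `tok_emb`, `seg_emb`, `pos_emb`, `stack01.Wq`, ..., `Wpred`).
#' @return Invisibly, `path`.
#' @export
save_model_params <- function(params, path) {
  saveRDS(.flatten_params(params), path)
  invisible(path)
}

#' Load (pretrained) weights from a flat named-tensor archive
#'
#' Validates every tensor's shape against the configuration; shape mismatches
#' and missing tensors abort with a message listing the offending names, and
#' tensors in the archive that map to nothing are reported.
#'
#' @param path Archive written by [save_model_params()] (or converted from an
#'   external checkpoint into the same container).
#' @param config A `"model_config"`.
#' @param mapping Optional named character vector translating archive tensor
#'   names to the canonical schema (`mapping["archive.name"] = "stack01.Wq"`).
#' @return Parameter list usable with [transformer_forward()].
#' @export
load_pretrained <- function(path, config, mapping = NULL) {
  flat <- readRDS(path)
  if (!is.null(mapping)) {
    hit <- names(flat) %in% names(mapping)
    names(flat)[hit] <- unname(mapping[names(flat)[hit]])
  }
  shapes <- .param_shapes(config)
  missing <- setdiff(names(shapes), names(flat))
  if (length(missing)) {
    stop("archive is missing tensor(s): ", paste(missing, collapse = ", "))
  }
  bad <- names(shapes)[vapply(names(shapes), function(nm) {
    !identical(as.integer(.shape_of(flat[[nm]])), as.integer(shapes[[nm]]))
  }, logical(1))]
  if (length(bad)) {
    stop("shape mismatch for tensor(s): ", paste(bad, collapse = ", "))
  }
  extra <- setdiff(names(flat), names(shapes))
  if (length(extra)) {
    message("unmapped tensor(s) ignored: ", paste(extra, collapse = ", "))
  }
  .unflatten_params(flat[names(shapes)], config)
}

#' Parameter counts per component
#'
#' @param config A `"model_config"`.
#' @return Named numeric vector of parameter counts (embeddings, per-stack
#'   attention and feed-forward, classifier, total).
#' @export
count_params <- function(config) {
  shapes <- .param_shapes(config)
  sizes <- vapply(shapes, prod, numeric(1))
  emb <- sum(sizes[c("tok_emb", "seg_emb", "pos_emb")])
  attn <- sum(sizes[grep("\\.(Wq|Wk|Wv|Wo|ln1_g|ln1_b)$", names(sizes))])
  ffn <- sum(sizes[grep("\\.(W1|b1|W2|b2|ln2_g|ln2_b)$", names(sizes))])
  c(embeddings = emb, attention = attn, feed_forward = ffn,
    classifier = sizes[["Wpred"]], total = sum(sizes))
}

#' Print a model size summary
#'
#' @param config A `"model_config"`.
#' @return Invisibly, the [count_params()] vector.
#' @export
describe_model <- function(config) {
  print(config)
  counts <- count_params(config)
  for (nm in names(counts)) {
    cat(sprintf("  %-14s %s\n", nm, format(counts[[nm]], big.mark = ",")))
  }
  invisible(counts)
}
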