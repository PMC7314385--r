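# Shared fixtures built in code, plus thin accessors for package internals
# exercised by the oracle tests.

.layer_norm_test <- function(X, g, b, eps) docrex:::.layer_norm(X, g, b, eps)$y
.flatten_params_test <- function(p) docrex:::.flatten_params(p)
.unflatten_params_test <- function(f, cfg) docrex:::.unflatten_params(f, cfg)
.forward_cached_test <- function(s, p, cfg) docrex:::.forward_cached(s, p, cfg)
.backward_cached_test <- function(fw, d, p, cfg) {
  docrex:::.backward_cached(fw, d, p, cfg)
}

toy_vocab <- function(extra = character(0)) {
  wordpiece_vocab(c("[PAD]", "[UNK]", "[CLS]", "[SEP]", extra))
}

# a small hand-built document with two sentences and two mention pairs
tiny_doc <- function() {
  title <- "A short report."
  abstract <- "Aspirin caused headache in one patient. Ibuprofen relieved fever quickly."
  text <- paste(title, abstract)
  at <- function(surface, raw_type, id) {
    s <- regexpr(surface, text, fixed = TRUE)[1] - 1L
    data.frame(start = s, end = s + nchar(surface), text = surface,
               type = NA_character_, raw_type = raw_type, concept_id = id,
               stringsAsFactors = FALSE)
  }
  mentions <- rbind(at("Aspirin", "Chemical", "C01"),
                    at("headache", "Disease", "Dh"),
                    at("Ibuprofen", "Chemical", "C02"),
                    at("fever", "Disease", "Df"))
  relations <- data.frame(type = "CID", concept_id_1 = "C01",
                          concept_id_2 = "Dh", stringsAsFactors = FALSE)
  new_document("42", title, abstract, mentions, relations)
}

random_token_sequence <- function(config, n_valid, max_len = n_valid,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(2L, sample(4:(config$vocab_size - 1L), n_valid - 2L,
                      replace = TRUE), 3L)
  structure(
    list(tokens = c("[CLS]", rep("w", n_valid - 2L), "[SEP]",
                    rep("[PAD]", max_len - n_valid)),
         ids = c(ids, rep(0L, max_len - n_valid)),
         positions = seq_len(max_len) - 1L,
         segment_ids = rep(0L, max_len),
         n = as.integer(max_len), n_valid = as.integer(n_valid)),
    class = "token_sequence")
}
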