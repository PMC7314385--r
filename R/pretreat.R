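# Entity pretreatment and WordPiece tokenization.
#
# Document-level instance construction makes instances from the same document
# share text while carrying different labels (the label-collision problem).
# Pretreatment breaks the collision: the replacement method rewrites target
# chemical/disease mentions to the uniform words "chemical"/"disease" (and
# non-target entity mentions to "entity"); the addition method wraps target
# mentions in boundary markers while keeping surface forms.

.collect_mention_rows <- function(inst, include_other = TRUE) {
  tm <- inst$target_mentions
  rows <- if (nrow(tm)) {
    data.frame(start = tm$start, end = tm$end, text = tm$text, type = tm$type,
               concept_id = tm$concept_id, role = tm$type,
               stringsAsFactors = FALSE)
  } else NULL
  om <- inst$other_mentions
  if (include_other && nrow(om)) {
    rows <- rbind(rows, data.frame(
      start = om$start, end = om$end, text = om$text, type = om$type,
      concept_id = om$concept_id, role = "other", stringsAsFactors = FALSE))
  }
  if (is.null(rows)) {
    rows <- data.frame(start = integer(0), end = integer(0),
                       text = character(0), type = character(0),
                       concept_id = character(0), role = character(0),
                       stringsAsFactors = FALSE)
  }
  rows
}

# Overlapping annotations cannot all be rewritten; keep the longest mention
# of each conflicting cluster (spec'd resolution) and warn.
.resolve_overlaps <- function(rows) {
  if (nrow(rows) < 2L) return(rows)
  ord <- order(-(rows$end - rows$start), rows$start)
  keep <- logical(nrow(rows))
  taken <- cbind(integer(0), integer(0))
  dropped <- 0L
  for (i in ord) {
    ov <- any(taken[, 1] < rows$end[i] & taken[, 2] > rows$start[i])
    if (ov) {
      dropped <- dropped + 1L
    } else {
      keep[i] <- TRUE
      taken <- rbind(taken, c(rows$start[i], rows$end[i]))
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d overlapping mention(s) dropped; longest kept", dropped),
            call. = FALSE)
  }
  out <- rows[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

.rebuild_instance <- function(inst, new_text, new_rows) {
  tm <- new_rows[new_rows$role != "other", , drop = FALSE]
  om <- new_rows[new_rows$role == "other", , drop = FALSE]
  strip <- function(df) {
    df <- df[, c("start", "end", "text", "type", "concept_id"), drop = FALSE]
    rownames(df) <- NULL
    df
  }
  out <- inst
  out$text <- new_text
  out$target_mentions <- strip(tm)
  out$other_mentions <- strip(om)
  .check_instance_offsets(out)
  out
}

#' Replacement pretreatment
#'
#' Rewrites every target chemical mention to `"chemical"`, every target
#' disease mention to `"disease"` and every non-target entity mention to
#' `"entity"`; non-mention text is unchanged and offsets are recomputed.
#' The operation is idempotent.  Overlapping mentions are resolved by
#' rewriting the longest mention and dropping (with a warning) the mentions
#' it covers.
#'
#' @param inst A `"rex_instance"`.
#' @param words Named character vector of replacement words for roles
#'   `chemical`, `disease` and `other`.
#' @return The pretreated `"rex_instance"` (attribute `pretreatment` set to
#'   `"replacement"`).
#' @export
apply_replacement <- function(inst,
                              words = c(chemical = "chemical",
                                        disease = "disease",
                                        other = "entity")) {
  rows <- .resolve_overlaps(.collect_mention_rows(inst))
  if (!nrow(rows)) {
    out <- inst
    attr(out, "pretreatment") <- "replacement"
    return(out)
  }
  res <- ""
  pos <- 0L
  orig_end <- rows$end  # end offsets are overwritten in-place below
  for (i in seq_len(nrow(rows))) {
    res <- paste0(res, substr(inst$text, pos + 1L, rows$start[i]))
    rep_word <- unname(words[[rows$role[i]]])
    rows$start[i] <- nchar(res)
    res <- paste0(res, rep_word)
    rows$end[i] <- nchar(res)
    rows$text[i] <- rep_word
    pos <- orig_end[i]
  }
  res <- paste0(res, substr(inst$text, pos + 1L, nchar(inst$text)))
  out <- .rebuild_instance(inst, res, rows)
  attr(out, "pretreatment") <- "replacement"
  out
}

#' Addition pretreatment
#'
#' Wraps target chemical mentions in `"[[ ... ]]"` and target disease
#' mentions in `"<< ... >>"` (space-separated markers); non-target mentions
#' and all surface forms are preserved.  Stripping the markers recovers the
#' original text exactly.
#'
#' @param inst A `"rex_instance"`.
#' @param markers Named list with elements `chemical` and `disease`, each a
#'   length-2 character vector of left/right boundary markers (non-empty and
#'   distinct per type).
#' @return The pretreated `"rex_instance"` (attribute `pretreatment` set to
#'   `"addition"`).
#' @export
apply_addition <- function(inst,
                           markers = list(chemical = c("[[", "]]"),
                                          disease = c("<<", ">>"))) {
  stopifnot(all(nzchar(unlist(markers))),
            !identical(markers$chemical, markers$disease))
  rows <- .resolve_overlaps(.collect_mention_rows(inst))
  if (!nrow(rows)) {
    out <- inst
    attr(out, "pretreatment") <- "addition"
    return(out)
  }
  res <- ""
  pos <- 0L
  orig_end <- rows$end
  for (i in seq_len(nrow(rows))) {
    res <- paste0(res, substr(inst$text, pos + 1L, rows$start[i]))
    surface <- rows$text[i]
    if (rows$role[i] %in% c("chemical", "disease")) {
      mk <- markers[[rows$role[i]]]
      res <- paste0(res, mk[1], " ")
      rows$start[i] <- nchar(res)
      res <- paste0(res, surface)
      rows$end[i] <- nchar(res)
      res <- paste0(res, " ", mk[2])
    } else {
      rows$start[i] <- nchar(res)
      res <- paste0(res, surface)
      rows$end[i] <- nchar(res)
    }
    pos <- orig_end[i]
  }
  res <- paste0(res, substr(inst$text, pos + 1L, nchar(inst$text)))
  out <- .rebuild_instance(inst, res, rows)
  attr(out, "pretreatment") <- "addition"
  out
}

#' Pretreat a list of instances
#'
#' @param instances List of `"rex_instance"` objects.
#' @param mode `"replacement"` or `"addition"`.
#' @param ... Passed to [apply_replacement()] or [apply_addition()].
#' @return List of pretreated instances.
#' @export
pretreat_instances <- function(instances,
                               mode = c("replacement", "addition"), ...) {
  mode <- match.arg(mode)
  f <- if (mode == "replacement") apply_replacement else apply_addition
  lapply(instances, f, ...)
}

## ---- WordPiece ------------------------------------------------------------

.wp_specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")

#' Construct a WordPiece vocabulary
#'
#' @param tokens Character vector of vocabulary tokens (one per line in the
#'   standard file format); continuation pieces carry the `"##"` prefix.
#' @return An object of class `"wordpiece_vocab"` with `tokens`, a hashed
#'   index and `size`.  Token ids are 0-based (line order).
#' @export
wordpiece_vocab <- function(tokens) {
  tokens <- as.character(tokens)
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary")
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = index)
  structure(list(tokens = tokens, index = index, size = length(tokens)),
            class = "wordpiece_vocab")
}

#' @export
print.wordpiece_vocab <- function(x, ...) {
  cat(sprintf("<wordpiece_vocab: %d tokens>\n", x$size))
  invisible(x)
}

#' Load a WordPiece vocabulary file (one token per line)
#'
#' @param path Vocabulary file path.
#' @return A `"wordpiece_vocab"`.
#' @export
load_wordpiece_vocab <- function(path) {
  wordpiece_vocab(readLines(path, warn = FALSE))
}

#' Look up token ids
#'
#' @param vocab A `"wordpiece_vocab"`.
#' @param tokens Character vector.
#' @return Integer vector of 0-based ids (`NA` for unknown tokens).
#' @export
vocab_id <- function(vocab, tokens) {
  vapply(tokens, function(tk) {
    v <- get0(tk, envir = vocab$index, inherits = FALSE)
    if (is.null(v)) NA_integer_ else v
  }, integer(1), USE.NAMES = FALSE)
}

.wp_word <- function(word, vocab, max_chars = 100L) {
  n <- nchar(word)
  if (n > max_chars) return("[UNK]")
  out <- character(0)
  i <- 1L
  while (i <= n) {
    found <- NA_character_
    for (j in n:i) {
      cand <- substr(word, i, j)
      if (i > 1L) cand <- paste0("##", cand)
      if (!is.na(vocab_id(vocab, cand))) {
        found <- cand
        i <- j + 1L
        break
      }
    }
    if (is.na(found)) return("[UNK]")
    out <- c(out, found)
  }
  out
}

#' Greedy longest-match-first WordPiece tokenization
#'
#' Splits text on whitespace, lowercases each word (uncased convention) and
#' applies greedy longest-match-first subword segmentation; continuation
#' pieces carry the `"##"` prefix.  A word with no matchable piece becomes
#' `"[UNK]"`.
#'
#' @param text Input string.
#' @param vocab A `"wordpiece_vocab"`.
#' @param lowercase Lowercase words before matching.
#' @return Character vector of word pieces (no `[CLS]`/`[SEP]`).
#' @export
wordpiece_tokenize <- function(text, vocab, lowercase = TRUE) {
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  if (lowercase) words <- tolower(words)
  unlist(lapply(words, .wp_word, vocab = vocab), use.names = FALSE)
}

#' Build the model-ready token sequence for one text
#'
#' Tokenizes with WordPiece, prepends `[CLS]`, appends `[SEP]` (sequences
#' longer than `max_len` keep the head: they are truncated to `max_len - 2`
#' content pieces before adding `[SEP]`), and pads with `[PAD]` to `max_len`
#' for batching.  Segment ids are a single constant (single-sequence input);
#' positions run `0..max_len-1`.
#'
#' @param text Input string.
#' @param vocab A `"wordpiece_vocab"` containing `[CLS]`, `[SEP]`, `[UNK]`
#'   and `[PAD]`.
#' @param max_len Maximum sequence length (>= 2).
#' @param lowercase Lowercase before matching.
#' @return An object of class `"token_sequence"`: list with `tokens`, `ids`
#'   (0-based), `positions`, `segment_ids`, `n` (= `max_len`) and `n_valid`
#'   (content length including `[CLS]`/`[SEP]`).
#' @export
tokenize_sequence <- function(text, vocab, max_len = 512L, lowercase = TRUE) {
  missing <- .wp_specials[is.na(vocab_id(vocab, .wp_specials))]
  if (length(missing)) {
    stop("vocabulary lacks special token(s): ", paste(missing, collapse = ", "))
  }
  if (max_len < 2L) stop("max_len must be at least 2")
  pieces <- wordpiece_tokenize(text, vocab, lowercase)
  if (length(pieces) > max_len - 2L) pieces <- pieces[seq_len(max_len - 2L)]
  tokens <- c("[CLS]", pieces, "[SEP]")
  n_valid <- length(tokens)
  if (n_valid < max_len) tokens <- c(tokens, rep("[PAD]", max_len - n_valid))
  structure(
    list(tokens = tokens, ids = vocab_id(vocab, tokens),
         positions = seq_len(max_len) - 1L,
         segment_ids = rep(0L, max_len), n = as.integer(max_len),
         n_valid = as.integer(n_valid)),
    class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence: %d/%d tokens: %s%s>\n", x$n_valid, x$n,
              paste(utils::head(x$tokens, 8), collapse = " "),
              if (x$n_valid > 8) " ..." else ""))
  invisible(x)
}

#' Tokenize pretreated instances
#'
#' @param instances List of `"rex_instance"` objects (typically pretreated).
#' @param vocab A `"wordpiece_vocab"`.
#' @param max_len Maximum sequence length.
#' @return List of `"token_sequence"` objects, each carrying the instance's
#'   `label`, `doc_id`, `chemical_id` and `disease_id`.
#' @export
tokenize_instances <- function(instances, vocab, max_len = 512L) {
  lapply(instances, function(inst) {
    seq <- tokenize_sequence(inst$text, vocab, max_len)
    seq$label <- inst$label
    seq$doc_id <- inst$doc_id
    seq$chemical_id <- inst$chemical_id
    seq$disease_id <- inst$disease_id
    seq
  })
}

#' Build a whole-word vocabulary from texts
#'
#' Collects the lowercased whitespace tokens of the supplied texts (or
#' instance texts); a token with trailing punctuation contributes its stem
#' plus a `"##"`-prefixed punctuation continuation piece, so e.g.
#' `"disease."` tokenizes as `disease ##.`.  Special tokens are prepended.
#' Intended for corpora whose vocabulary is closed (synthetic corpora, small
#' experiments); for real biomedical text load a released WordPiece
#' vocabulary with [load_wordpiece_vocab()] instead.
#'
#' @param x Character vector of texts, or a list of `"rex_instance"` objects.
#' @return A `"wordpiece_vocab"`.
#' @export
build_vocab <- function(x) {
  texts <- if (is.character(x)) x else vapply(x, `[[`, "", "text")
  words <- tolower(unlist(strsplit(trimws(texts), "\\s+"), use.names = FALSE))
  words <- unique(words[nzchar(words)])
  m <- regexec("^(.*[a-z0-9])([^a-z0-9]+)$", words)
  parts <- regmatches(words, m)
  split_ok <- lengths(parts) == 3L
  stems <- vapply(parts[split_ok], `[`, "", 2L)
  conts <- vapply(parts[split_ok], `[`, "", 3L)
  whole <- words[!split_ok]
  wordpiece_vocab(c(.wp_specials,
                    sort(unique(c(whole, stems))),
                    sort(unique(paste0("##", conts)))))
}
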