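# PubTator plain-text corpus I/O and sentence segmentation.
#
# Dialect: documents are blocks separated by blank lines.  Each block starts
# with "<id>|t|<title>" and optionally "<id>|a|<abstract>", followed by
# tab-separated mention lines (id, start, end, text, type, concept_id) and
# relation lines (id, relation_type, concept_id_1, concept_id_2).  Character
# offsets are 0-based, half-open, over the concatenated
# "title + single space + abstract" string.

.normalize_entity_type <- function(raw) {
  t <- tolower(raw)
  out <- rep("other", length(t))
  out[t == "chemical"] <- "chemical"
  out[t == "disease"] <- "disease"
  out
}

.empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0), text = character(0),
             type = character(0), raw_type = character(0),
             concept_id = character(0), stringsAsFactors = FALSE)
}

.empty_relations <- function() {
  data.frame(type = character(0), concept_id_1 = character(0),
             concept_id_2 = character(0), stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' A document holds the full `title + " " + abstract` text together with its
#' typed entity mentions (0-based half-open character offsets, normalized
#' concept identifiers) and gold document-level relations.
#'
#' @param doc_id Document identifier string.
#' @param title Title text (non-empty).
#' @param abstract Abstract text (may be empty).
#' @param mentions Data frame with columns `start`, `end`, `text`, `type`
#'   (one of `"chemical"`, `"disease"`, `"other"`), `raw_type` (the surface
#'   type string written back to PubTator) and `concept_id`.
#' @param relations Data frame with columns `type`, `concept_id_1`,
#'   `concept_id_2`.  Duplicate rows are removed.
#' @param validate If `TRUE`, offset integrity is checked and violations abort.
#' @return An object of class `"rex_document"`: a list with fields `doc_id`,
#'   `title`, `abstract`, `text`, `mentions` (sorted by start offset) and
#'   `relations`.
#' @export
new_document <- function(doc_id, title, abstract = "",
                         mentions = .empty_mentions(),
                         relations = .empty_relations(),
                         validate = TRUE) {
  if (!nzchar(title)) stop("document ", doc_id, ": title must be non-empty")
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  if (nrow(mentions)) {
    if (is.null(mentions$raw_type)) mentions$raw_type <- mentions$type
    mentions$type <- .normalize_entity_type(mentions$raw_type)
    mentions$type[mentions$concept_id == "-1"] <- "other"
    mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
    rownames(mentions) <- NULL
  } else {
    mentions <- .empty_mentions()
  }
  relations <- unique(relations)
  rownames(relations) <- NULL
  doc <- structure(
    list(doc_id = as.character(doc_id), title = title, abstract = abstract,
         text = text, mentions = mentions, relations = relations),
    class = "rex_document")
  if (validate) {
    problems <- validate_document(doc)
    if (length(problems)) {
      stop("document ", doc_id, " failed validation:\n  ",
           paste(problems, collapse = "\n  "))
    }
  }
  doc
}

#' Validate a document's annotation integrity
#'
#' Checks that mention offsets are 0-based half-open over the document text,
#' that every slice reproduces the annotated surface string, and that
#' relations are well formed.  Relations whose concept identifiers never occur
#' among the mentions are reported (they are legal but cannot be labeled).
#'
#' @param doc An object created by [new_document()] or [read_pubtator()].
#' @return Character vector of problems; `character(0)` if the document is
#'   clean.
#' @export
validate_document <- function(doc) {
  problems <- character(0)
  men <- doc$mentions
  n <- nchar(doc$text)
  if (!nzchar(doc$text)) problems <- c(problems, "empty text")
  if (nrow(men)) {
    for (i in seq_len(nrow(men))) {
      if (is.na(men$start[i]) || is.na(men$end[i]) ||
          men$start[i] < 0 || men$start[i] >= men$end[i] || men$end[i] > n) {
        problems <- c(problems, sprintf(
          "mention '%s' has invalid offsets [%s, %s)",
          men$text[i], men$start[i], men$end[i]))
        next
      }
      slice <- substr(doc$text, men$start[i] + 1L, men$end[i])
      if (!identical(slice, men$text[i])) {
        problems <- c(problems, sprintf(
          "mention '%s' at [%d, %d) does not match text slice '%s'",
          men$text[i], men$start[i], men$end[i], slice))
      }
    }
  }
  rel <- doc$relations
  if (nrow(rel)) {
    known <- unique(men$concept_id)
    for (i in seq_len(nrow(rel))) {
      if (!(rel$concept_id_1[i] %in% known) ||
          !(rel$concept_id_2[i] %in% known)) {
        problems <- c(problems, sprintf(
          "relation %s(%s, %s) references a concept with no mentions",
          rel$type[i], rel$concept_id_1[i], rel$concept_id_2[i]))
      }
    }
  }
  problems
}

#' @export
print.rex_document <- function(x, ...) {
  cat(sprintf("<rex_document %s: %d chars, %d mentions, %d relations>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

.as_lines <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x) && !grepl("\n", x, fixed = TRUE)) {
      return(readLines(x, warn = FALSE))
    }
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}

#' Read a PubTator-format corpus
#'
#' Parses annotated abstracts in PubTator plain-text format into a list of
#' documents.  Composite concept annotations listing several identifiers
#' separated by `|` are expanded into one mention per identifier sharing the
#' same offsets.  Mentions with concept id `"-1"` (unnormalized) are kept with
#' type `"other"` and never form target pairs downstream.
#'
#' @param x Path to a file, a single string containing the corpus, or a
#'   character vector of lines.
#' @return List of `"rex_document"` objects (possibly empty).  Malformed lines
#'   raise a parse error naming the line number; offset/text mismatches raise
#'   an integrity error naming the mention.
#' @seealso [write_pubtator()]
#' @export
read_pubtator <- function(x) {
  lines <- .as_lines(x)
  if (!length(lines)) return(list())
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) return(list())
  grp <- cumsum(c(TRUE, diff(nonblank) > 1L))
  blocks <- split(nonblank, grp)
  lapply(blocks, function(idx) .parse_pubtator_block(lines[idx], idx))
}

.parse_pubtator_block <- function(blines, lnos) {
  doc_id <- NULL
  title <- NULL
  abstract <- ""
  men <- list()
  rel <- list()
  for (i in seq_along(blines)) {
    line <- blines[i]
    lno <- lnos[i]
    if (grepl("^[^\t|]+\\|t\\|", line)) {
      doc_id <- sub("\\|.*$", "", line)
      title <- sub("^[^|]+\\|t\\|", "", line)
      next
    }
    if (grepl("^[^\t|]+\\|a\\|", line)) {
      abstract <- sub("^[^|]+\\|a\\|", "", line)
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 4L) {
      rel[[length(rel) + 1L]] <- data.frame(
        type = fields[2], concept_id_1 = fields[3], concept_id_2 = fields[4],
        stringsAsFactors = FALSE)
    } else if (length(fields) %in% 5:7) {
      start <- suppressWarnings(as.integer(fields[2]))
      end <- suppressWarnings(as.integer(fields[3]))
      if (is.na(start) || is.na(end)) {
        stop(sprintf("PubTator parse error at line %d: non-numeric offsets in '%s'",
                     lno, line))
      }
      concept <- if (length(fields) >= 6L) fields[6] else "-1"
      ids <- trimws(strsplit(concept, "|", fixed = TRUE)[[1]])
      ids <- ids[nzchar(ids)]
      if (!length(ids)) ids <- "-1"
      for (id in ids) {
        men[[length(men) + 1L]] <- data.frame(
          start = start, end = end, text = fields[4],
          type = NA_character_, raw_type = fields[5], concept_id = id,
          stringsAsFactors = FALSE)
      }
    } else {
      stop(sprintf("PubTator parse error at line %d: '%s'", lno, line))
    }
  }
  if (is.null(title)) {
    stop(sprintf("PubTator parse error at line %d: block without a title line",
                 lnos[1]))
  }
  mentions <- if (length(men)) do.call(rbind, men) else .empty_mentions()
  relations <- if (length(rel)) do.call(rbind, rel) else .empty_relations()
  doc <- new_document(doc_id, title, abstract, mentions, relations,
                      validate = FALSE)
  men_problems <- grep("^mention", validate_document(doc), value = TRUE)
  if (length(men_problems)) {
    stop("document ", doc_id, " integrity error:\n  ",
         paste(men_problems, collapse = "\n  "))
  }
  doc
}

#' Write documents in PubTator format
#'
#' Emits the same dialect accepted by [read_pubtator()]; reading the output
#' back reproduces the documents (round-trip stable up to field ordering).
#'
#' @param docs List of `"rex_document"` objects.
#' @param path File path, or `NULL` to return the lines invisibly without
#'   writing.
#' @return Invisibly, the character vector of emitted lines.
#' @export
write_pubtator <- function(docs, path = NULL) {
  lines <- unlist(lapply(docs, .format_pubtator_block), use.names = FALSE)
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

.format_pubtator_block <- function(doc) {
  out <- paste0(doc$doc_id, "|t|", doc$title)
  if (nzchar(doc$abstract)) out <- c(out, paste0(doc$doc_id, "|a|", doc$abstract))
  men <- doc$mentions
  if (nrow(men)) {
    out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc$doc_id,
                          men$start, men$end, men$text, men$raw_type,
                          men$concept_id))
  }
  rel <- doc$relations
  if (nrow(rel)) {
    out <- c(out, sprintf("%s\t%s\t%s\t%s", doc$doc_id, rel$type,
                          rel$concept_id_1, rel$concept_id_2))
  }
  c(out, "")
}

.abbreviations <- c("e.g", "i.e", "cf", "vs", "etc", "fig", "figs", "eq",
                    "eqs", "dr", "mr", "mrs", "ms", "prof", "no", "al",
                    "approx", "ca", "resp", "inc", "ltd", "st", "jr", "sr")

#' Segment a document into sentences
#'
#' Rule-based splitter on terminal punctuation followed by whitespace, with an
#' abbreviation guard (common abbreviations and single initials never end a
#' sentence).  Any boundary that would bisect a mention is removed by merging
#' the adjacent spans, so every mention lies fully within exactly one
#' sentence.  The degenerate one-sentence segmentation is always a legal
#' fallback, so the operation never fails on valid documents.
#'
#' @param doc A `"rex_document"`.
#' @return An object of class `"sentence_segmentation"`: a list with `spans`
#'   (data frame of 0-based half-open character intervals, non-overlapping and
#'   ascending) and `mention_sentence` (integer vector mapping each row of
#'   `doc$mentions` to a 1-based sentence index).
#' @export
split_sentences <- function(doc) {
  text <- doc$text
  nc <- nchar(text)
  m <- gregexpr("[.!?]+[\"')\\]]*", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1] != -1) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      e <- m[i] + len[i] - 1L
      if (e >= nc) next
      if (!grepl("^\\s$", substr(text, e + 1L, e + 1L))) next
      if (identical(substr(text, m[i], e), ".")) {
        context <- substr(text, max(1L, m[i] - 20L), m[i] - 1L)
        before <- sub("^.*?(\\S*)$", "\\1", context)
        w <- tolower(gsub("[^a-zA-Z]", "", before))
        if (nchar(w) == 1L || w %in% .abbreviations) next
      }
      bounds <- c(bounds, e)
    }
  }
  spans <- list()
  sent_start <- 1L
  for (b in bounds) {
    spans[[length(spans) + 1L]] <- c(sent_start, b)
    rest_ws <- attr(regexpr("^\\s+", substr(text, b + 1L, nc)), "match.length")
    sent_start <- b + 1L + max(rest_ws, 0L)
  }
  if (sent_start <= nc) {
    e <- nc
    while (e >= sent_start && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    if (e >= sent_start) spans[[length(spans) + 1L]] <- c(sent_start, e)
  }
  if (!length(spans)) spans <- list(c(1L, nc))
  sp <- data.frame(start = vapply(spans, `[`, 1L, 1L) - 1L,
                   end = vapply(spans, `[`, 1L, 2L))
  men <- doc$mentions
  # remove any boundary that bisects a mention by merging the spans it crosses
  if (nrow(men)) {
    repeat {
      merged <- FALSE
      for (j in seq_len(nrow(men))) {
        ov <- which(sp$start < men$end[j] & sp$end > men$start[j])
        if (length(ov) > 1L) {
          lo <- min(ov); hi <- max(ov)
          sp <- rbind(
            sp[seq_len(lo - 1L), , drop = FALSE],
            data.frame(start = sp$start[lo], end = sp$end[hi]),
            sp[seq_len(nrow(sp)) > hi, , drop = FALSE])
          rownames(sp) <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  mention_sentence <- integer(nrow(men))
  for (j in seq_len(nrow(men))) {
    hit <- which(sp$start <= men$start[j] & sp$end >= men$end[j])
    if (!length(hit)) hit <- which(sp$start < men$end[j] & sp$end > men$start[j])
    mention_sentence[j] <- hit[1]
  }
  structure(list(spans = sp, mention_sentence = mention_sentence),
            class = "sentence_segmentation")
}

#' @export
print.sentence_segmentation <- function(x, ...) {
  cat(sprintf("<sentence_segmentation: %d sentences, %d mentions mapped>\n",
              nrow(x$spans), length(x$mention_sentence)))
  invisible(x)
}
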