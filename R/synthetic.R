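# Synthetic PubTator corpora with planted, learnable relation structure.
#
# The generator emulates the structural properties of document-level
# annotated abstracts (CDR-style): multi-sentence texts, chemical and disease
# concepts with one or more mentions each at exact character offsets, and
# gold relations annotated per concept pair per document.  Positive pairs
# carry a lexical cue: a trigger word planted between a dedicated chemical
# and disease mention, either within one sentence or split across adjacent
# sentences (cross-sentence evidence).  Negative pairs receive a distractor
# word in the same construction, so after replacement pretreatment the only
# discriminative signal is the local pattern "chemical <cue> disease".  Text
# is templated English-like filler; realism is out of scope — only offsets,
# multi-sentence mention hulls and cue placement matter for testing.

.syn_filler <- c(
  "patient", "patients", "treatment", "therapy", "dose", "daily", "clinical",
  "course", "after", "during", "with", "without", "severe", "mild", "acute",
  "chronic", "admission", "hospital", "recovery", "baseline", "weeks", "days",
  "symptoms", "signs", "levels", "serum", "plasma", "renal", "hepatic",
  "cardiac", "function", "normal", "elevated", "reduced", "history", "onset",
  "examination", "findings", "therapy", "outcome")

.syn_chemicals <- c(
  "amoxicillin", "ibuprofen", "metformin", "lisinopril", "warfarin",
  "digoxin", "prednisone", "fluoxetine", "haloperidol", "cisplatin",
  "gentamicin", "phenytoin", "lithium", "propranolol", "simvastatin",
  "omeprazole", "rifampicin", "carbamazepine", "tacrolimus", "methotrexate")

.syn_diseases <- c(
  "nephrotoxicity", "hepatitis", "seizures", "hypotension", "bradycardia",
  "rash", "nausea", "anemia", "renal failure", "liver injury",
  "qt prolongation", "heart failure", "muscle pain", "hearing loss",
  "memory loss", "skin necrosis", "bone loss", "lung fibrosis",
  "visual impairment", "weight gain")

.nonce_word <- function(n_chars = 7L) {
  paste(sample(letters, n_chars, replace = TRUE), collapse = "")
}

#' Synthetic corpus configuration
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Integer range (min, max) of abstract sentences.
#' @param chemicals_per_doc,diseases_per_doc Integer ranges of distinct
#'   concepts per document.
#' @param mentions_per_concept Integer range of base mentions per concept
#'   (cue/distractor constructions add one further mention of each involved
#'   concept).
#' @param positive_rate Probability that a candidate pair carries a gold
#'   relation.
#' @param cross_sentence_fraction Probability that a pair's cue construction
#'   spans two adjacent sentences rather than one.
#' @param cue_strength Probability that the cue (or, for negatives, the
#'   distractor) construction is emitted at all.
#' @param cue_lexicon Trigger words for positive pairs.
#' @param distractor_lexicon Words planted in the same construction for
#'   negative pairs.
#' @param nonce_entities Use random nonce surface forms instead of the
#'   built-in chemical/disease lexicons.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_docs = 100L,
                             sentences_per_doc = c(5L, 10L),
                             chemicals_per_doc = c(1L, 2L),
                             diseases_per_doc = c(1L, 3L),
                             mentions_per_concept = c(1L, 2L),
                             positive_rate = 0.25,
                             cross_sentence_fraction = 0.3,
                             cue_strength = 1.0,
                             cue_lexicon = c("induced", "caused",
                                             "triggered", "provoked"),
                             distractor_lexicon = c("coadministered",
                                                    "monitored",
                                                    "accompanied",
                                                    "preceded"),
                             nonce_entities = FALSE,
                             seed = 1L) {
  probs <- c(positive_rate, cross_sentence_fraction, cue_strength)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  ranges <- list(sentences_per_doc, chemicals_per_doc, diseases_per_doc,
                 mentions_per_concept)
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) stop("invalid range")
  }
  if (n_docs < 0L) stop("n_docs must be non-negative")
  max_concepts <- chemicals_per_doc[2] + diseases_per_doc[2]
  if (max_concepts > sentences_per_doc[2] * 6L) {
    stop("infeasible configuration: more concepts than the sentences can host")
  }
  structure(
    list(n_docs = as.integer(n_docs),
         sentences_per_doc = as.integer(sentences_per_doc),
         chemicals_per_doc = as.integer(chemicals_per_doc),
         diseases_per_doc = as.integer(diseases_per_doc),
         mentions_per_concept = as.integer(mentions_per_concept),
         positive_rate = positive_rate,
         cross_sentence_fraction = cross_sentence_fraction,
         cue_strength = cue_strength, cue_lexicon = cue_lexicon,
         distractor_lexicon = distractor_lexicon,
         nonce_entities = isTRUE(nonce_entities), seed = as.integer(seed)),
    class = "synthetic_config")
}

.sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# A sentence is a data frame of entries; an entry is one or more words
# emitted verbatim (joined by single spaces) and optionally annotated as a
# mention of a concept.
.entry <- function(word, type = NA_character_, concept = NA_character_) {
  data.frame(word = word, type = type, concept = concept,
             stringsAsFactors = FALSE)
}

.insert_entries <- function(sent, at, rows) {
  n <- nrow(sent)
  rbind(sent[seq_len(at), , drop = FALSE], rows,
        sent[seq_len(n) > at, , drop = FALSE])
}

.generate_document <- function(cfg, doc_num) {
  ns <- .sample_range(cfg$sentences_per_doc)
  sents <- lapply(seq_len(ns), function(i) {
    .entry(sample(.syn_filler, .sample_range(c(4L, 8L)), replace = TRUE))
  })
  n_chem <- .sample_range(cfg$chemicals_per_doc)
  n_dis <- .sample_range(cfg$diseases_per_doc)
  surf <- function(lexicon, k) {
    if (cfg$nonce_entities) {
      vapply(seq_len(k), function(i) .nonce_word(), character(1))
    } else {
      sample(lexicon, k)
    }
  }
  chem <- data.frame(id = sprintf("C%04d", (doc_num - 1L) * 50L + seq_len(n_chem)),
                     surface = surf(.syn_chemicals, n_chem),
                     stringsAsFactors = FALSE)
  dis <- data.frame(id = sprintf("D%04d", (doc_num - 1L) * 50L + seq_len(n_dis)),
                    surface = surf(.syn_diseases, n_dis),
                    stringsAsFactors = FALSE)
  plant <- function(surface, type, concept) {
    s <- sample(ns, 1L)
    at <- sample(0:nrow(sents[[s]]), 1L)
    sents[[s]] <<- .insert_entries(sents[[s]], at,
                                   .entry(surface, type, concept))
  }
  for (i in seq_len(n_chem)) {
    for (j in seq_len(.sample_range(cfg$mentions_per_concept))) {
      plant(chem$surface[i], "Chemical", chem$id[i])
    }
  }
  for (i in seq_len(n_dis)) {
    for (j in seq_len(.sample_range(cfg$mentions_per_concept))) {
      plant(dis$surface[i], "Disease", dis$id[i])
    }
  }
  relations <- .empty_relations()
  # cue/distractor constructions claim exclusive sentences so one pair's
  # planted adjacency pattern can never be broken by another pair's insertion
  run_used <- logical(ns)
  for (i in seq_len(n_chem)) {
    for (j in seq_len(n_dis)) {
      positive <- stats::runif(1) < cfg$positive_rate
      if (positive) {
        relations <- rbind(relations, data.frame(
          type = "CID", concept_id_1 = chem$id[i], concept_id_2 = dis$id[j],
          stringsAsFactors = FALSE))
      }
      if (stats::runif(1) < cfg$cue_strength) {
        word <- if (positive) sample(cfg$cue_lexicon, 1L) else
          sample(cfg$distractor_lexicon, 1L)
        cross <- ns >= 2L && stats::runif(1) < cfg$cross_sentence_fraction
        cross_free <- which(!run_used[-ns] & !run_used[-1L])
        intra_free <- which(!run_used)
        if (cross && length(cross_free)) {
          s <- cross_free[sample.int(length(cross_free), 1L)]
          run_used[c(s, s + 1L)] <- TRUE
          sents[[s]] <- rbind(
            sents[[s]],
            .entry(chem$surface[i], "Chemical", chem$id[i]),
            .entry(word))
          sents[[s + 1L]] <- rbind(
            .entry(dis$surface[j], "Disease", dis$id[j]),
            sents[[s + 1L]])
        } else {
          s <- if (length(intra_free)) {
            intra_free[sample.int(length(intra_free), 1L)]
          } else sample(ns, 1L)
          run_used[s] <- TRUE
          at <- sample(0:nrow(sents[[s]]), 1L)
          sents[[s]] <- .insert_entries(
            sents[[s]], at,
            rbind(.entry(chem$surface[i], "Chemical", chem$id[i]),
                  .entry(word),
                  .entry(dis$surface[j], "Disease", dis$id[j])))
        }
      }
    }
  }
  title <- paste0(paste(sample(.syn_filler, 5L), collapse = " "), ".")
  mentions <- .empty_mentions()
  cursor <- nchar(title) + 1L  # abstract starts after "title + space"
  sent_strings <- character(ns)
  for (s in seq_len(ns)) {
    entries <- sents[[s]]
    off <- cursor
    for (e in seq_len(nrow(entries))) {
      if (!is.na(entries$concept[e])) {
        mentions <- rbind(mentions, data.frame(
          start = off, end = off + nchar(entries$word[e]),
          text = entries$word[e], type = NA_character_,
          raw_type = entries$type[e], concept_id = entries$concept[e],
          stringsAsFactors = FALSE))
      }
      off <- off + nchar(entries$word[e]) + 1L
    }
    sent_strings[s] <- paste0(paste(entries$word, collapse = " "), ".")
    cursor <- cursor + nchar(sent_strings[s]) + 1L
  }
  new_document(as.character(10000L + doc_num), title,
               paste(sent_strings, collapse = " "), mentions, relations)
}

#' Generate a synthetic PubTator corpus
#'
#' Fully deterministic given `cfg$seed`; every document passes
#' [validate_document()] with zero problems, gold relations are recorded at
#' concept-pair (document) level, and positive pairs carry their lexical cue
#' with probability `cue_strength`, placed across sentences with probability
#' `cross_sentence_fraction`.
#'
#' @param cfg A `"synthetic_config"`.
#' @return List of `"rex_document"` objects.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_docs), function(i) .generate_document(cfg, i))
}

#' Detect the planted relation cue in replacement-pretreated text
#'
#' After replacement pretreatment the planted signal of [generate_corpus()]
#' is the local pattern `chemical <cue> disease` (the cue word flanked by the
#' replaced target words, with at most a sentence boundary after the cue).
#' This rule classifier certifies that the planted signal is separable before
#' any encoder is trained: at `cue_strength = 1` it labels the corpus
#' perfectly.
#'
#' @param text Replacement-pretreated instance text.
#' @param cues Cue lexicon used at generation time.
#' @return Logical: cue pattern present.
#' @export
cue_pattern_present <- function(text,
                                cues = c("induced", "caused", "triggered",
                                         "provoked")) {
  pattern <- paste0("\\bchemical (", paste(cues, collapse = "|"),
                    ")\\.? disease\\b")
  grepl(pattern, text)
}

.mention_at <- function(text, surface, raw_type, concept_id,
                        occurrence = 1L) {
  m <- gregexpr(surface, text, fixed = TRUE)[[1]]
  if (m[1] == -1 || length(m) < occurrence) {
    stop("fixture error: surface not found: ", surface)
  }
  start <- m[occurrence] - 1L
  data.frame(start = start, end = start + nchar(surface), text = surface,
             type = NA_character_, raw_type = raw_type,
             concept_id = concept_id, stringsAsFactors = FALSE)
}

#' Structural case-report fixture
#'
#' A document with the entity/relation structure of a published amisulpride
#' overdose case report: two chemical concepts (amisulpride C1, calcium
#' gluconate C2) and four disease concepts (overdose D1, prolonged QT
#' syndrome / QT prolongation D2, poisoning D3, hypocalcemia D4) spread over
#' four abstract sentences, with gold CID relations C1-D2 and C1-D4.  The
#' sentences are paraphrased; only the annotation structure matters: the
#' C1-D2 mention hull spans all four abstract sentences and the C1-D4 hull
#' spans the first three, so pair enumeration yields 2 x 4 = 8 instances of
#' which exactly 2 are positive.
#'
#' @return A `"rex_document"`.
#' @export
fixture_case_report <- function() {
  title <- "Case reports from an emergency department."
  s <- c("Two cases of amisulpride overdose resulting in prolonged QT syndrome.",
         "Severe poisoning was evident in both patients on admission.",
         "Intravenous calcium gluconate corrected the hypocalcemia in both cases.",
         "The QT prolongation resolved after supportive care.")
  abstract <- paste(s, collapse = " ")
  text <- paste(title, abstract)
  mentions <- rbind(
    .mention_at(text, "amisulpride", "Chemical", "C1"),
    .mention_at(text, "overdose", "Disease", "D1"),
    .mention_at(text, "prolonged QT syndrome", "Disease", "D2"),
    .mention_at(text, "poisoning", "Disease", "D3"),
    .mention_at(text, "calcium gluconate", "Chemical", "C2"),
    .mention_at(text, "hypocalcemia", "Disease", "D4"),
    .mention_at(text, "QT prolongation", "Disease", "D2"))
  relations <- data.frame(type = c("CID", "CID"),
                          concept_id_1 = c("C1", "C1"),
                          concept_id_2 = c("D2", "D4"),
                          stringsAsFactors = FALSE)
  new_document("100001", title, abstract, mentions, relations)
}

#' Side-effects sentence fixture (token-distance worked example)
#'
#' The sentence comparing side-effect profiles of dothiepin and
#' amitriptyline, annotated with its chemical and disease mentions.  Under
#' whitespace tokenization the distance between "blurred vision" and
#' "amitriptyline" is 12 tokens, which is what makes a distance-threshold
#' heuristic (threshold 10) discard this sentence even though it is the only
#' sentence asserting that relation.
#'
#' @return List with `text` (the sentence), `mentions` (offsets relative to
#'   the sentence) and `document` (a `"rex_document"` whose abstract is the
#'   sentence, with a gold CID relation between amitriptyline and blurred
#'   vision).
#' @export
fixture_side_effects_sentence <- function() {
  sentence <- paste0(
    "The overall incidence of side effects and the frequency and severity ",
    "of blurred vision, dry mouth, and drowsiness were significantly less ",
    "with dothiepin than with amitriptyline.")
  men_rel <- rbind(
    .mention_at(sentence, "blurred vision", "Disease", "D1"),
    .mention_at(sentence, "dry mouth", "Disease", "D2"),
    .mention_at(sentence, "drowsiness", "Disease", "D3"),
    .mention_at(sentence, "dothiepin", "Chemical", "C1"),
    .mention_at(sentence, "amitriptyline", "Chemical", "C2"))
  title <- "Comparison of two antidepressant side-effect profiles."
  men_doc <- men_rel
  shift <- nchar(title) + 1L
  men_doc$start <- men_doc$start + shift
  men_doc$end <- men_doc$end + shift
  relations <- data.frame(type = "CID", concept_id_1 = "C2",
                          concept_id_2 = "D1", stringsAsFactors = FALSE)
  doc <- new_document("100002", title, sentence, men_doc, relations)
  list(text = sentence, mentions = men_rel, document = doc)
}

#' Pretreatment worked-example instance
#'
#' A single-sentence instance whose target pair is (amisulpride, prolonged QT
#' syndrome) with the non-target entity mention "overdose".  Replacement
#' pretreatment rewrites it to "Two cases of chemical entity: a cause for
#' disease"; addition pretreatment yields
#' "Two cases of [[ amisulpride ]] overdose: a cause for
#' << prolonged QT syndrome >>".
#'
#' @return A `"rex_instance"` labeled `"CID"`.
#' @export
fixture_pretreatment_instance <- function() {
  text <- "Two cases of amisulpride overdose: a cause for prolonged QT syndrome"
  target <- rbind(
    .mention_at(text, "amisulpride", "Chemical", "C1"),
    .mention_at(text, "prolonged QT syndrome", "Disease", "D2"))
  other <- .mention_at(text, "overdose", "Disease", "D1")
  fix_tab <- function(df) {
    df$type <- .normalize_entity_type(df$raw_type)
    df[, c("start", "end", "text", "type", "concept_id")]
  }
  structure(
    list(doc_id = "100003", chemical_id = "C1", disease_id = "D2",
         sentence_range = c(1L, 1L), text = text,
         target_mentions = fix_tab(target), other_mentions = fix_tab(other),
         label = "CID"),
    class = "rex_instance")
}
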