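---
title: "Document-level biomedical relation extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Document-level biomedical relation extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docrex)
```

## The problem

Corpora such as the BioCreative V chemical-disease relation (CDR) corpus
annotate relations at the *document* level: a gold chemical-induced disease
(CID) relation is asserted between two concept identifiers (e.g. MeSH IDs)
for a whole abstract, without saying which sentence carries the evidence.
The evidence frequently crosses sentence boundaries, so sentence-level
relation classifiers do not apply directly.

A common workaround splits such corpora into intra-sentence instances
(co-sentential mention pairs within a token-distance threshold, typically
10) and inter-sentence instances for the remaining pairs.  The split is
lossy in both directions: a perfectly good co-sentential assertion at
distance 12 is discarded, and pairs with an intra-sentence instance have all
their cross-sentence evidence thrown away.  `heuristic_split()` implements
this baseline precisely so that its failure modes can be demonstrated — the
package's own preprocessing never splits.

## Instance construction

For every candidate pair — each distinct (chemical concept, disease concept)
combination among a document's mentions — `build_instance()` takes the
contiguous block of sentences from the first to the last sentence containing
a mention of *either* target concept (the tight min/max hull over all their
mentions, including every sentence in between) and joins it into one
instance.  The gold label transfers one-to-one from the document's relation
annotation for that pair; nothing needs to be relabeled at sentence level.
Two consequences matter:

* different pairs in one document get different hulls, so context is kept
  per pair and unrelated sentences are dropped;
* instances from the same document can share identical text while carrying
  different labels (the label-collision problem), which pretreatment must
  resolve.

Mentions with unnormalized concept id `-1` are kept as type `other` and
never form pairs; composite annotations (`D001|D002`) expand into one
mention per concept.  Relations whose concepts never occur as mentions
cannot label any instance and are dropped with a warning — real corpora
contain such rows, and aborting would be worse than reporting.

Sentence segmentation is rule-based (terminal punctuation + whitespace with
an abbreviation guard).  No splitter is canonical for this task; the binding
constraint is mention integrity, so any boundary that would bisect a mention
is removed by merging the adjacent spans.  Corpus statistics that depend on
sentence counts (e.g. mean sentences per instance) are therefore
splitter-relative, and `instance_stats()` reports whitespace-token lengths —
and WordPiece lengths when a vocabulary is supplied — because published
length tables do not say which convention they use.

## Entity pretreatment

Two treatments are implemented on instances:

* **Replacement** (`apply_replacement()`): target chemical mentions become
  the word `chemical`, target disease mentions become `disease`, and
  non-target entity mentions become `entity`.  Uniform words free the
  encoder from rare compound biomedical surface forms and mark *which* pair
  is the target, which is exactly what breaks the label collision: two
  instances with identical raw text but different target pairs rewrite to
  different texts.  The operation is idempotent and recomputes all offsets.
* **Addition** (`apply_addition()`): target chemicals are wrapped in
  `[[ ... ]]` and target diseases in `<< ... >>`, keeping surface forms;
  non-target mentions are untouched.  Stripping the markers recovers the
  original text exactly.

Overlapping annotations cannot all be rewritten; the longest mention wins
and the conflict is logged — overlaps signal annotation problems that should
be visible, not silently absorbed.

## The encoder

The classifier is a transformer encoder written from scratch in base R
matrix algebra.  The input is the sum of token, segment and position
embeddings for the WordPiece sequence `[CLS] ... [SEP]`; each of the `k`
stacks applies `h`-head scaled dot-product attention

$$A = \mathrm{softmax}\!\left(\frac{(SW^Q)(SW^K)^\top}{\sqrt{l}}\right),
\qquad O_h = A\,(SW^V), \qquad l = d/h,$$

concatenates the head outputs, projects them (`d x d`), and applies residual
connection + layer normalization, followed by a position-wise two-layer ReLU
feed-forward network (inner width `m = 4d`) with its own residual + layer
normalization.  Class scores are a linear map of the final-stack `[CLS]`
row; training minimizes softmax cross-entropy (the standard choice for a
linear classification head) with exact analytic backpropagation, verified in
the tests against central finite differences and explicit-loop oracles.

Design points that were genuinely open:

* **Attention scale.**  The scale is `sqrt(l)`, the per-head dimension: it
  is the quantity that keeps the logit variance invariant to the number of
  heads for unit-variance inputs (a property the tests check empirically).
* **Sub-layer completeness.**  The minimal published block omits the output
  projection after head concatenation and the residual/normalization around
  the feed-forward sub-layer; the reference encoder family (BERT/SciBERT)
  includes both.  Both variants are supported via
  `model_config(variant =)`; `"standard"` is the default because the
  pretrained encoders whose weights `load_pretrained()` ingests require
  those tensors.  Matrix conformability also forces the head output to be
  `n x l` and the merged output `n x d`.
* **Padding.**  Only the valid positions of a sequence enter the encoder,
  which is mathematically identical to masking padded keys out of every
  softmax; appending `[PAD]` tokens can never change the `[CLS]` scores
  (tested).
* **Numerics.**  Softmax is computed with row-max subtraction; layer
  normalization uses population variance with `eps = 1e-12`; dropout
  (default rate 0.1) is inverted dropout applied to sub-layer outputs during
  training only.  `[CLS]` is position 1 of the sequence.

`load_pretrained()` reads a flat named-tensor archive (`tok_emb`,
`stack01.Wq`, ..., `Wpred`), validates every shape against the
configuration, and reports unmapped tensors; a name mapping translates
externally converted checkpoints.  Pretraining itself is out of scope.

## Training configuration

`train_config()` defaults follow the reference fine-tuning recipe: 3
epochs, Adam, linear learning-rate decay after a 10% warm-up, global
gradient-norm clipping at 1.0, results averaged over 5 seeded runs (run *r*
uses `seed + r - 1`).  Document-level corpora use sequence length 512 with
batch size 6; the sentence-level DDI- and CPR-style settings are 150/32 and
200/23.  The default rate `2e-5` is a *fine-tuning* rate; training a small
model from random initialization needs around `1e-3` together with a larger
initialization scale (`init_sd = 0.1`; `0.02` is the pretrained-regime
value).  Position embeddings start from scaled sinusoids (still trainable):
the fixed phase structure makes relative-offset attention linearly
representable from step one, which substantially accelerates from-scratch
training; the random start remains available.  Class imbalance is left
unweighted.  Truncation keeps the head of an instance — target mentions
concentrate at the start of the span because the span is their hull.

Evaluation reports per-class and micro precision/recall/F1 in percent, with
the negative ("no relation") class excluded from the evaluated set;
`length_binned_eval()` repeats the evaluation in bins of 50 whitespace
tokens of the untreated instance text, the convention that published length
distributions are consistent with.  `attention_report()` exports the
per-head attention rows of `[CLS]` and the target-entity tokens at any
stack for downstream visualization (rendering itself is out of scope).

## The synthetic corpus generator

`generate_corpus()` emulates the *structural* properties of a document-level
annotated corpus: multi-sentence abstracts, chemical/disease concepts with
one or more mentions at exact character offsets, gold relations per concept
pair, and a controllable lexical signal.  A positive pair plants a trigger
word between a dedicated chemical and disease mention, within one sentence
or split across two adjacent ones (`cross_sentence_fraction`, default 0.3);
a negative pair plants a distractor word in the same construction, so after
replacement the only discriminative feature is the local pattern
`chemical <cue> disease`.  Cue constructions claim exclusive sentences so
one pair's pattern can never be corrupted by another's insertion.  Text is
English-like filler; realism (MeSH semantics, hypernymy, co-reference,
discontinuous mentions) is deliberately absent, so green tests certify the
machinery, not performance on real abstracts.

Defaults: 5–10 sentences per document, 1–2 chemical and 1–3 disease
concepts, 1–2 base mentions per concept, positive rate 0.25, cue strength
1.0 — values in the range of what document-level biomedical corpora exhibit.

One structural fact discovered while validating the generator is worth
recording: with several candidate pairs per document, *no* word-presence
rule can label instances perfectly, because an instance covers every
sentence between its hull endpoints and therefore contains sibling pairs'
cue words (with the sibling's mentions rewritten to `entity`).  The
certification that the planted signal is separable before any encoder is
trained — a rule classifier on the cue pattern reaching 100% training
accuracy — and the tiny-model learnability experiment therefore use
single-pair documents (1 chemical x 1 disease), where cue presence and
label coincide exactly.  Multi-pair corpora remain the default everywhere
else and are what the collision and hull tests exercise.

## Problem sizes used by the test suite

The learnability experiment trains `k = 2, h = 2, d = 32` on 500 instances
(560 single-pair documents, 60 held out) for 3 epochs at batch size 1,
learning rate `1e-3` — about ten seconds on one CPU — and checks ≥95%
training accuracy and a ≥20-point F1 margin over the majority baseline on
the held-out split.  The replacement-vs-addition comparison trains the same
model on 200 nonce-entity instances per mode and asserts non-inferiority of
replacement within 2 F1 points, mirroring the directional finding that
uniform replacement words help document-level extraction.  Encoder oracles
run at `n ≤ 6, d ≤ 8, h ∈ {1,2}, k ≤ 2` against scalar-loop
reimplementations at tolerance `1e-8`.

## Known limitations

* The full 12-stack, 768-dimensional configuration is constructible and
  correct but not practical to *train* in plain R; realistic use of that
  size is inference with converted pretrained weights.
* WordPiece here operates on whitespace-split words; it does not split
  punctuation into separate basic tokens, so a released vocabulary will
  tokenize slightly differently than tokenizers that do.
* The sentence splitter is deliberately simple; documents with unusual
  punctuation degrade gracefully toward coarser (merged) sentences, never
  toward broken mentions.
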