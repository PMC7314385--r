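# docrex

Document-level biomedical relation extraction in R: from PubTator-annotated
abstracts to trained relation classifiers, without splitting the corpus into
intra- and inter-sentence halves.

## The problem

Corpora like the BioCreative V chemical-disease relation (CDR) corpus
annotate chemical-induced disease (CID) relations per *document*: a gold
relation links two concept identifiers for a whole abstract, and the
evidence may cross sentence boundaries. Sentence-level classifiers do not
apply, and the common fix — keeping co-sentential mention pairs only when
their token distance is below a threshold (10) and treating leftovers as
inter-sentence — discards valid evidence (a perfectly good assertion at
distance 12 is thrown away) and introduces labeling noise.

`docrex` instead builds **one instance per candidate entity pair**: the
contiguous block of sentences from the first to the last sentence containing
a mention of either target concept (the min/max hull over all their
mentions). Gold labels transfer one-to-one from the document annotation. A
**pretreatment** step then rewrites entity mentions — either *replacement*
(target chemical → `chemical`, target disease → `disease`, other entities →
`entity`) or *addition* (`[[ ... ]]` / `<< ... >>` boundary markers) — which
resolves the collision where instances share text but differ in label. A
multi-head self-attention encoder classifies the instance from its `[CLS]`
representation:

```
A   = softmax( (S Wq)(S Wk)ᵀ / √l ),  l = d/h        (per head)
O_h = A (S Wv);  M = LN(S + [O_1;…;O_h] Wo);  S' = LN(M + FFN(M))
c   = Wpred · s_[CLS]     after k stacks
```

The encoder, its exact backpropagation (Adam, warm-up, linear decay,
gradient clipping), WordPiece tokenization, PubTator I/O, P/R/F1 and
length-binned evaluation, attention export, and a synthetic corpus
generator with planted relation cues are all implemented in the package;
pretrained weights can be ingested from a flat named-tensor archive
(`load_pretrained()` validates shapes and accepts a name mapping for
converted public checkpoints — see the schema in `?save_model_params`).

## Worked example

```r
library(docrex)

doc <- fixture_case_report()        # 2 chemical x 4 disease concepts
seg <- split_sentences(doc)
pairs <- enumerate_entity_pairs(doc)
nrow(pairs)
#> [1] 8
inst <- lapply(seq_len(nrow(pairs)), function(i)
  build_instance(doc, seg, pairs$chemical_id[i], pairs$disease_id[i]))
table(vapply(inst, `[[`, "", "label"))
#>      CID negative
#>        2        6
inst[[2]]                           # pair (C1, D2)
#> <rex_instance 100001 (C1, D2) sentences 2-5 label=CID>
```

Eight instances — every chemical-disease concept combination — of which the
two annotated pairs are positive; the (C1, D2) instance covers the four
sentences spanned by those concepts' mentions (one more trailing sentence
than (C1, D4), whose hull ends earlier).

```r
ex <- fixture_pretreatment_instance()
apply_replacement(ex)$text
#> [1] "Two cases of chemical entity: a cause for disease"
apply_addition(ex)$text
#> [1] "Two cases of [[ amisulpride ]] overdose: a cause for << prolonged QT syndrome >>"

fx <- fixture_side_effects_sentence()
token_distance(fx$text,
               fx$mentions[fx$mentions$text == "blurred vision", ],
               fx$mentions[fx$mentions$text == "amitriptyline", ])
#> [1] 12
```

That distance of 12 is why a threshold-10 heuristic discards the only
sentence asserting the relation — `heuristic_split()` reproduces the
baseline's behavior for comparison.

Training end to end on synthetic data (about ten seconds on one CPU):

```r
cfg  <- synthetic_config(n_docs = 560, chemicals_per_doc = c(1, 1),
                         diseases_per_doc = c(1, 1), seed = 20)
inst <- build_instances(generate_corpus(cfg))
rep_inst <- pretreat_instances(inst, "replacement")
vocab <- build_vocab(rep_inst)
seqs  <- tokenize_instances(rep_inst[1:500], vocab, max_len = 128)
mcfg  <- model_config(k = 2, h = 2, d = 32, n_max = 128,
                      vocab_size = vocab$size, dropout = 0)
fit   <- train_model(init_params(mcfg, seed = 42, init_sd = 0.1), mcfg, seqs,
                     train_config(epochs = 3, batch_size = 1, lr = 1e-3))
pred  <- predict_model(fit$params, mcfg,
                       tokenize_instances(rep_inst[501:560], vocab, 128))
evaluate_predictions(pred$labels, vapply(inst[501:560], `[[`, "", "label"))
```

`length_binned_eval()` repeats the evaluation in 50-token bins of instance
length, and `attention_report()` exports the per-head attention rows of
`[CLS]` and the target-entity tokens for visualization.

A thin shell front end covers the data-side verbs
(`inst/cli/docrex validate|synth|preprocess|pretreat|stats|describe|train|eval`).

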