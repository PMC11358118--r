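---
title: "Methods: hybrid neural + rule extraction of PICOS evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid neural + rule extraction of PICOS evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picosminer)
```

## The extraction problem

Reports of randomized controlled trials (RCTs) in Chinese-language
journals carry ten recurring evidence elements organised by the PICOS
framework — Population (participant count, age, case source, diagnostic
criteria), Intervention/Comparison (therapy), Outcome (adverse events,
shedding count), and Study design (missing data, blinding, randomization).
Each element has a characteristic output granularity, typed here as a
level: **A** long sentence (diagnostic criteria), **B** short sentence
(source, therapy, blinding, randomization), **C** phrase (age, adverse
events), **D** number (participant count, shedding, missing data).

Pure rule systems locate such values precisely when the phrasing is
anticipated but miss paraphrases and fire on look-alike background
sentences; pure sequence labelers find the right regions but blur
boundaries and emit coarse text. The package therefore composes the two:
the labeler anchors a region, the rules refine it.

## Sequence labeling model

Text is tokenized per Unicode character — the standard choice for Chinese
named-entity recognition, which avoids committing to any word segmenter —
and cut into segments of at most 128 characters, preferring
sentence-final punctuation (。；！？) as cut points. At training time a
cut that would bisect a gold annotation is shifted back to the span
start; at prediction time no gold exists and the plain rule applies.

Each segment is labeled with BIO tags (`B-e`/`I-e` per element plus `O`;
21 tags for the 10-element schema, 31 for the extended schema that splits
the five group-specific elements into treatment/control variants). The
model is a linear-chain conditional random field over trainable character
embeddings and a bidirectional LSTM:

* emissions: embedding (default 32-dim) → forward + backward LSTM
  (default 48 units each) → linear projection to per-tag scores;
* transitions: a learned $(K{+}2)\times(K{+}2)$ matrix with virtual
  START/STOP states; with `bio_constraints = TRUE` (default) the illegal
  BIO transitions (into `I-e` from anything but `B-e`/`I-e`) are masked
  and behave as $-\infty$ in all scoring, so decoded output is always
  schema-valid;
* loss: exact negative log-likelihood by the forward algorithm; gradients
  come from forward–backward marginals and flow through the LSTM by
  backpropagation through time (implemented in C++ via Rcpp, as the
  per-timestep recurrence is the one part of the package that profits
  from compiled code);
* optimization: AdamW (default learning rate 0.005, weight decay 0.01,
  batch size 8, 10 epochs). Gradients are accumulated
  sequence-by-sequence within a batch and applied in one step, which
  gives the same semantics as padding with masked positions without the
  bookkeeping;
* data split: segments are shuffled with the training seed and split
  9:1 train/held-out; the held-out strict entity F1 is logged per epoch.

All numerics are in log space with max-shift stabilization; the pure-R
reference implementations (`crf_log_partition()`, `crf_sequence_score()`,
`crf_nll()`, `viterbi_decode()`) are tested against exhaustive path
enumeration to $10^{-8}$ and the C++ gradient against finite differences.
Viterbi ties break toward the lowest tag index so decoding is
deterministic. Training is fully determined by the seed; checkpoints
reload with bit-identical predictions.

A pretrained contextual encoder can replace the trainable
embedding+BiLSTM stack through the external-encoder adapter: any function
mapping a character vector to fixed-dimension per-character vectors can be
passed as `encoder`, in which case only the emission projection and the
CRF transitions are trained. The default stack keeps the package fully
offline.

Hyperparameters worth tuning on real data: `embed_dim`/`hidden_dim`
(capacity; the defaults suit template-like corpora), `learning_rate`
(0.001–0.01 is a sensible band for AdamW here), `epochs` (watch the
held-out F1 trajectory in `$history`), and `bio_constraints` (leave on).

## Rule refinement

A rule set is an ordered list of element-keyed Unicode regular
expressions with three actions, tried in (priority, rule id) order per
span:

* `judge` — a gate: if the span text fails the judge pattern for its
  element the span is vetoed. The gate is veto-only and never
  re-classifies; of the two readings of a boolean gate (must-match vs
  must-not-match) the must-match form was chosen because it lets one
  cheap plausibility pattern (e.g. "mentions a medical facility" for the
  case-source element) protect precision without enumerating failure
  modes.
* `match` — first match wins; the refined value is the **full** match,
  and its offsets become the scored span. Anchored patterns thus trim
  trailing redundancy off a labeler span.
* `split` — one refined value per named capture group (used for
  treatment/control pairs such as 治疗组60例，对照组58例).

Unmatched spans pass through with `rule_id = "fallback"`: since
downstream readers tolerate redundant characters, discarding unmatched
model output would throw information away. Refinement never widens: every
non-fallback value is a substring of its raw span.

For D-level (number) elements the numeric reading is `parse_numeric()` of
the first named capture group if the winning rule declares one, else of
the whole value. This convention lets a `match` rule keep the full
evidence phrase for span-level scoring while still yielding the bare
number (Arabic or simple Chinese numerals over 〇一二三四五六七八九十百)
for the structured record.

The rules-only baseline scans every sentence of the raw document
(sentences split on 。；！？) with first-match-wins per element and
sentence; `judge` rules do not participate there, as they gate spans, not
sentences. The shipped starter set (two or more rules per element, 21
rules) is
co-designed with the synthetic templates; it is a demonstration
inventory, not a curated production rule base.

## Evaluation

Entity-level scoring uses TP/FP/FN tallies per element with greedy
one-to-one matching in document order. `strict` requires identical
(element, start, end). `relaxed` operationalizes "trailing redundancy
does not change the reading": the gold interval must be contained in the
prediction and the surplus may not exceed
`max(tol_abs, tol_frac * |gold|)` (defaults 10 characters and 0.5). Both
knobs are exposed; strict is the default in reports. Relaxed counts
dominate strict by construction. Micro-averaged P/R/F1 (all counts
pooled) is the headline number; per-element rows are reported in registry
order.

Annotation quality control uses Cohen's kappa on a two-rater 2×2 table,
$\kappa = (p_o - p_e)/(1 - p_e)$, with the degenerate case $p_e = 1$
defined as $\kappa = 1$ (it can only arise with perfect agreement in a
2×2 table). The diagonal agreement proportions are reported **truncated**
(not rounded) to two decimals — with the benchmark table
`[[1746, 118], [56, 504]]` the both-accurate cell is 72.0297%, reported
as 72.02% — matching the convention under which such proportions are
conventionally quoted alongside the kappa.

## The synthetic corpus

`generate_corpus()` renders each document from a typed-slot template bank:
per element one evidence sentence (slot types: integers — occasionally as
Chinese numerals — age ranges, institution names, therapy phrases,
criteria sentences), plus distractor sentences from a fixed neutral pool,
shuffled together. Defaults define the reference study conditions: every
element included with probability 0.9, four distractors per document, 1%
OCR-like character substitution outside gold spans, 500 documents for the
reference corpus. Three RNG streams (structure, slots, noise) derive from
the master seed so changing one knob does not reshuffle the rest.

Two design features make the generator a meaningful testbed rather than a
tautology:

* **Traps.** The distractor pool contains sentences that superficially
  match a starter rule (a "previous study enrolled N patients" sentence,
  a literature-reported adverse event) but are never annotated. Rules
  alone must produce false positives on them; the labeler can use
  context to avoid them. This reproduces, qualitatively, the
  rules-only precision deficit.
* **Uncovered paraphrases.** Some A/B/C-level templates are deliberately
  phrased outside the rule inventory, giving rules-only a recall deficit
  while the labeler learns them. D-level templates are all rule-covered,
  so on noise-free corpora rules-only recall on number elements is
  exactly 1 — a co-design invariant the tests assert.

`inject_ocr_noise()` emulates character-level OCR corruption (one-to-one
substitutions from a confusion alphabet, gold spans protected, offsets
preserved); `inject_redundancy()` derives boundary-redundant prediction
sets from gold (rightward extension by 1..k\_max characters) to exercise
the strict/relaxed gap.

What the generator does **not** emulate: real lexical diversity (slot
pools are small, so the labeler's near-perfect synthetic scores say
nothing about absolute performance on real corpora), document layout and
PDF artifacts, disease-mix distributions, annotation disagreement, and
entity nesting. Passing the pipeline's ordering properties (hybrid ≥
labeler-only F1, hybrid ≥ rules-only precision under strict matching)
demonstrates the *mechanics* — anchoring, refinement, filtering — not
field performance. An ASCII-transliterated bank (with its own mirrored
starter rules) is included for terminals without CJK fonts; its sentences
end with the CJK full stop so the segmenter and sentence scanner apply
unchanged.

## Problem sizes and runtime

The reference configuration — 500 documents, ≈1,000 segments, ≈4,500 gold
spans — trains the default labeler in under two minutes on one CPU and
reaches held-out strict entity F1 above 0.99 within three epochs; the
whole acceptance computation (generation, training, three extraction
modes, scoring) takes about two and a half minutes. Oracle suites use 100
random CRF lattices (L ≤ 5, K ≤ 5) against exhaustive enumeration and
1,000 fuzzed span sets for the matching properties.

## Known limitations

* The starter rules and templates are co-designed; applying the package
  to real corpora requires authoring a domain rule set (the JSON format
  is the stable interface) and annotating training text.
* `judge` rules gate whole spans; they cannot re-classify an element or
  veto individual split values.
* The sentence scanner and segmenter treat 。；！？ as the only sentence
  terminators; Arabic decimal points are safe, but Western sentence
  punctuation in mixed-language text is not treated as a boundary.
* Document ids follow the `NUMBER_YEAR_AUTHOR_TITLE` convention but are
  not parsed; metadata extraction is out of scope, as are PDF/OCR
  ingestion and database retrieval.
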