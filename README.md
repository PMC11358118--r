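# picosminer

Systematic reviewers of traditional Chinese medicine (TCM) randomized
controlled trials need ten PICOS evidence elements pulled out of every
report: participant count, age, case source, diagnostic criteria, therapy,
adverse events, shedding (drop-out) count, missing data, blinding, and
randomization method. **picosminer** extracts them from Chinese RCT text
with a hybrid pipeline:

1. **Neural labeling.** A character-level BiLSTM-CRF tags each ≤128-character
   text segment with BIO labels over the ten elements (21 tags; an extended
   treatment/control schema with 15 entity labels and 31 tags is included).
   For a tag path $y_1..y_L$ with emission scores $E$ and transition scores
   $T$, the linear-chain CRF scores
   $s(y) = T_{\mathrm{START},y_1} + \sum_i E_{i,y_i} + \sum_i T_{y_i,y_{i+1}} + T_{y_L,\mathrm{STOP}}$,
   trains on the negative log-likelihood
   $\log \sum_{y'} e^{s(y')} - s(y)$ (forward algorithm), and decodes with
   Viterbi under BIO-constraint masking.
2. **Rule refinement.** An ordered, element-keyed rule set
   `PATTERN = {Pattern1, Pattern2, …}` of Unicode regular expressions
   refines each predicted span: `match` keeps the full pattern match,
   `judge` gates (vetoes) implausible spans, `split` emits one value per
   named capture group; unmatched spans pass through as `fallback`.
   Number-level (D) values are parsed to numerics, including simple Chinese
   numerals (六十 → 60).
3. **Evaluation.** Entity-level Recall = TP/(TP+FN),
   Precision = TP/(TP+FP), F1 = 2PR/(P+R) under *strict* (exact offsets)
   or *relaxed* matching (gold contained in prediction, bounded trailing
   surplus — redundant characters that do not change the reading), plus
   Cohen's kappa for two-rater annotation quality control.

A seeded synthetic-corpus generator renders annotated Chinese RCT
paragraphs from typed-slot templates (with distractor and "trap" sentences,
OCR-like character noise, and boundary-redundancy perturbations), so the
whole pipeline trains and evaluates offline in minutes on one CPU.

## Worked example

```r
library(picosminer)

# Annotation quality: two raters classify 2,424 sampled annotations as
# accurate/ambiguous; the agreement table gives
cohens_kappa(matrix(c(1746, 56, 118, 504), 2, 2))
#> Cohen's kappa: 0.806 (observed 0.9282, expected 0.6309, n = 2424)

# Synthetic corpus, rule-only baseline on one document
corp  <- generate_corpus(generator_config(n_docs = 5, seed = 42))
doc   <- corp$documents[[1]]
rules <- compile_ruleset(system.file("extdata", "starter_rules.json",
                                     package = "picosminer"))
picos_record(doc$doc_id, rules_only_extract(doc$text, rules), "rule-only")
#> <picos_record> 0001_2007_李娜_中药治疗临床观察 (rule-only): 7 value(s)
#>   pop_number     [145,153) 共纳入59例患者 = 59 (pn_enroll)
#>   pop_source     [87,107) 病例来源于广州中医药大学第一附属医院门诊 (src_from)
#>   pop_diagnosis  [108,138) 诊断参照中医病证诊断疗效标准相关标准执行，由两名医师独立判定 (diag_ref)
#>   therapy        [33,45) 治疗组予以补中益气汤治疗 (ther_use)
#>   out_adverse    [54,62) 未见明显不良反应 (ae_none)
#>   out_shedding   [65,73) 9例患者中途退出 = 9 (shed_quit)
#>   des_blind      [79,86) 采用双盲法设计 (blind_design)
```

Each line is one refined value: element, half-open character offsets, the
extracted text, the parsed numeric for number-level elements, and the rule
that produced it. The document has six gold spans; the extra `pop_number`
hit at [145,153) illustrates the rule-only failure mode: it comes from a
background sentence ("既往一项研究共纳入59例患者…", a *previous* study,
not annotated as gold) — a false positive the neural labeler learns to
reject from context. Paraphrased evidence outside the pattern inventory is
the converse failure (missed by rules, learned by the labeler).
`hybrid_extract(doc, model, rules)` runs the full model-then-rules
pipeline and `evaluate_extraction()` scores any mode against gold:

```r
model  <- crf_labeler(corp$documents, corp$schema, epochs = 10, seed = 1)
hybrid <- lapply(corp$documents, hybrid_extract, model = model, ruleset = rules)
evaluate_extraction(corp$documents, hybrid, match_config("strict"))
```

A command-line wrapper (`inst/cli/picosminer`) exposes the same flow as
`generate`, `train`, `extract`, `evaluate` and `kappa` subcommands.

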