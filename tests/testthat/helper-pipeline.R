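# The reference end-to-end fixture: the seed-42 synthetic study (500
# documents, generator defaults) with a labeler trained at the default
# schedule. Built lazily once and shared across tests that examine the
# trained pipeline.
.pipeline_cache <- new.env(parent = emptyenv())

reference_pipeline <- function() {
  if (!is.null(.pipeline_cache$fx)) return(.pipeline_cache$fx)
  corp <- generate_corpus(generator_config(n_docs = 500, seed = 42))
  model <- crf_labeler(corp$documents, corp$schema, epochs = 10, seed = 1)
  rules <- starter_ruleset()
  .pipeline_cache$fx <- list(corpus = corp, model = model, rules = rules)
  .pipeline_cache$fx
}
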