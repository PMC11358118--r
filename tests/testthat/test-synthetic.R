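test_that("generation is deterministic given the seed", {
  c1 <- generate_corpus(generator_config(n_docs = 6, seed = 42))
  c2 <- generate_corpus(generator_config(n_docs = 6, seed = 42))
  expect_identical(vapply(c1$documents, `[[`, character(1), "text"),
                   vapply(c2$documents, `[[`, character(1), "text"))
  expect_identical(c1$documents[[3]]$spans, c2$documents[[3]]$spans)
  c3 <- generate_corpus(generator_config(n_docs = 6, seed = 43))
  expect_false(identical(c1$documents[[1]]$text, c3$documents[[1]]$text))
})

test_that("changing the noise rate does not reshuffle document structure", {
  clean <- generate_corpus(generator_config(n_docs = 5, seed = 8,
                                            ocr_noise_rate = 0))
  noisy <- generate_corpus(generator_config(n_docs = 5, seed = 8,
                                            ocr_noise_rate = 0.2))
  for (i in 1:5) {
    expect_identical(clean$documents[[i]]$spans$element,
                     noisy$documents[[i]]$spans$element)
    expect_identical(clean$documents[[i]]$spans$start,
                     noisy$documents[[i]]$spans$start)
    # gold text itself is protected from noise
    expect_identical(clean$documents[[i]]$spans$text,
                     noisy$documents[[i]]$spans$text)
  }
})

test_that("inclusion probability 1 yields every element in every document", {
  corp <- generate_corpus(generator_config(n_docs = 10, seed = 3,
                                           include_prob = 1))
  reg <- element_registry()
  for (d in corp$documents) {
    expect_setequal(unique(d$spans$element), reg$id)
  }
})

test_that("gold offsets address the rendered span under all noise settings", {
  for (rate in c(0, 0.05, 0.3)) {
    corp <- generate_corpus(generator_config(n_docs = 6, seed = 13,
                                             ocr_noise_rate = rate))
    for (d in corp$documents) {
      expect_identical(picosminer:::slice_text(d$text, d$spans$start,
                                               d$spans$end),
                       d$spans$text)
      # document segments partition the text
      expect_identical(paste(vapply(d$segments, function(s)
        paste(s$chars, collapse = ""), character(1)), collapse = ""), d$text)
    }
  }
})

test_that("generated corpora survive the BIO dialect losslessly", {
  corp <- generate_corpus(generator_config(n_docs = 5, seed = 29))
  p <- withr::local_tempfile(fileext = ".bio")
  write_bio_corpus(corp$documents, p)
  back <- read_bio_corpus(p, schema = corp$schema)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$text, corp$documents[[i]]$text)
    expect_identical(back[[i]]$spans$start, corp$documents[[i]]$spans$start)
    expect_identical(back[[i]]$spans$element,
                     corp$documents[[i]]$spans$element)
  }
})

test_that("a template bank missing an enabled element is rejected", {
  bank <- load_template_bank()
  bank$elements$des_random <- NULL
  cfg <- generator_config(n_docs = 2, seed = 1, template_bank = bank)
  expect_error(generate_corpus(cfg), "des_random")
})

test_that("OCR noise respects rate extremes and the seed", {
  doc <- picos_document("d1", strrep("统计分析采用软件完成。", 4),
                        spans = entity_spans("therapy", 0, 4,
                                             text = "统计分析", level = "B"),
                        schema = tag_schema(element_registry()))
  same <- inject_ocr_noise(doc, 0, seed = 5)
  expect_identical(same$text, doc$text)
  full <- inject_ocr_noise(doc, 1, seed = 5)
  ch0 <- chars_of(doc$text)
  ch1 <- chars_of(full$text)
  expect_identical(ch1[1:4], ch0[1:4]) # gold span protected
  expect_true(all(ch1[5:length(ch1)] != ch0[5:length(ch0)]))
  again <- inject_ocr_noise(doc, 1, seed = 5)
  expect_identical(full$text, again$text)
  expect_false(identical(inject_ocr_noise(doc, 1, seed = 6)$text, full$text))
})

test_that("redundancy injection extends spans rightward within k_max", {
  corp <- generate_corpus(generator_config(n_docs = 4, seed = 44))
  d <- corp$documents[[1]]
  same <- inject_redundancy(d$spans, nchar(d$text), rate = 0, k_max = 3,
                            seed = 2)
  expect_equal(same$end, d$spans$end)
  ext <- inject_redundancy(d$spans, nchar(d$text), rate = 1, k_max = 3,
                           seed = 2)
  grew <- attr(ext, "extended")
  expect_true(all(ext$end[grew] > d$spans$end[grew]))
  expect_true(all(ext$end - d$spans$end <= 3))
  expect_true(all(ext$end <= nchar(d$text)))
  expect_identical(ext,
                   inject_redundancy(d$spans, nchar(d$text), 1, 3, seed = 2))
  # spans that could not extend are exactly the non-grown ones
  blocked <- d$spans$end == nchar(d$text)
  expect_true(all(grew | blocked))
})

test_that("rule-only recall is 1.0 on D-level elements of noise-free corpora", {
  corp <- generate_corpus(generator_config(n_docs = 25, seed = 61,
                                           ocr_noise_rate = 0))
  rs <- starter_ruleset()
  preds <- lapply(corp$documents, function(d) {
    picos_record(d$doc_id, rules_only_extract(d$text, rs), "rule-only")
  })
  res <- evaluate_extraction(corp$documents, preds, match_config("strict"))
  d_rows <- res$per_element[res$per_element$element %in%
                              c("pop_number", "out_shedding", "des_missing"), ]
  expect_true(all(d_rows$recall == 1))
})

test_that("the ASCII-transliterated bank drives the same machinery", {
  cfg <- generator_config(n_docs = 4, seed = 10, template_bank = "ascii",
                          ocr_noise_rate = 0)
  corp <- generate_corpus(cfg)
  expect_length(corp$documents, 4L)
  rs <- compile_ruleset(system.file("extdata", "starter_rules_ascii.json",
                                    package = "picosminer"))
  preds <- lapply(corp$documents, function(d) {
    picos_record(d$doc_id, rules_only_extract(d$text, rs), "rule-only")
  })
  res <- evaluate_extraction(corp$documents, preds, match_config("strict"))
  d_rows <- res$per_element[res$per_element$element %in%
                              c("pop_number", "out_shedding", "des_missing"), ]
  expect_true(all(d_rows$recall == 1))
})
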