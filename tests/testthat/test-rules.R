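reg <- element_registry()

test_that("ruleset compilation validates patterns, ids and elements", {
  rs <- starter_ruleset()
  expect_s3_class(rs, "ruleset")
  expect_setequal(unique(rs$element), reg$id)
  # ordering is (element in registry order, priority, rule_id)
  expect_equal(rs$rule_id[rs$element == "pop_source"][1], "src_judge")

  expect_error(compile_ruleset(list(list(rule_id = "r1", element = "pop_age",
                                         pattern = "([", action = "match"))),
               "r1")
  expect_error(compile_ruleset(list(
    list(rule_id = "r1", element = "pop_age", pattern = "a", action = "match"),
    list(rule_id = "r1", element = "pop_age", pattern = "b", action = "match"))),
    "duplicate")
  expect_error(compile_ruleset(list(list(rule_id = "r1", element = "nope",
                                         pattern = "a", action = "match"))),
               "registry")
  expect_error(compile_ruleset(list(list(rule_id = "r1", element = "pop_age",
                                         pattern = "a", action = "split"))),
               "named group")
})

test_that("split rules emit one value per named group", {
  rs <- compile_ruleset(list(
    list(rule_id = "pn", element = "pop_number",
         pattern = "共?纳入(?P<n>\\d+)例", action = "split", priority = 1),
    list(rule_id = "pn2", element = "pop_number",
         pattern = "治疗组(?P<n_t>\\d+)例，对照组(?P<n_c>\\d+)例",
         action = "split", priority = 2)))
  span <- entity_spans("pop_number", 0, 8, text = "共纳入120例患者",
                       level = "D")
  vals <- apply_rules_to_span(span, rs)
  expect_length(vals, 1L)
  expect_equal(vals[[1]]$value, "120")
  expect_equal(vals[[1]]$numeric, 120)
  expect_equal(vals[[1]]$rule_id, "pn")
  expect_equal(vals[[1]]$start, 3L)
  expect_equal(vals[[1]]$end, 6L)

  span2 <- entity_spans("pop_number", 10, 24,
                        text = "治疗组60例，对照组58例", level = "D")
  vals2 <- apply_rules_to_span(span2, rs)
  expect_equal(vapply(vals2, `[[`, character(1), "value"), c("60", "58"))
  expect_equal(vapply(vals2, `[[`, numeric(1), "numeric"), c(60, 58))
})

test_that("unmatched spans fall through; judge rules veto", {
  rs <- starter_ruleset()
  span <- entity_spans("pop_number", 5, 9, text = "一些别的话", level = "D")
  vals <- apply_rules_to_span(span, rs)
  expect_length(vals, 1L)
  expect_equal(vals[[1]]$rule_id, "fallback")
  expect_equal(vals[[1]]$value, "一些别的话")
  expect_equal(vals[[1]]$start, 5L)
  # pop_source span without a facility word fails the judge gate
  vetoed <- apply_rules_to_span(
    entity_spans("pop_source", 0, 4, text = "来源不明", level = "B"), rs)
  expect_length(vetoed, 0L)
  kept <- apply_rules_to_span(
    entity_spans("pop_source", 0, 12, text = "病例来源于某某医院门诊",
                 level = "B"), rs)
  expect_equal(kept[[1]]$rule_id, "src_from")
})

test_that("refinement never widens a span (value stays inside the raw text)", {
  set.seed(12)
  corp <- generate_corpus(generator_config(n_docs = 15, seed = 12,
                                           ocr_noise_rate = 0))
  rs <- starter_ruleset()
  for (i in seq_along(corp$documents)) {
    spans <- corp$documents[[i]]$spans
    for (j in seq_len(nrow(spans))) {
      for (v in apply_rules_to_span(spans[j, ], rs)) {
        expect_gte(v$start, spans$start[j])
        expect_lte(v$end, spans$end[j])
        if (v$rule_id != "fallback") {
          expect_true(grepl(v$value, spans$text[j], fixed = TRUE))
        }
      }
    }
  }
})

test_that("rules-only extraction scans sentences of the raw document", {
  rs <- starter_ruleset()
  txt <- "前言内容。共纳入88例患者，随机分为治疗组与对照组。随访期间失访3例。"
  vals <- rules_only_extract(txt, rs)
  els <- vapply(vals, `[[`, character(1), "element")
  expect_setequal(els, c("pop_number", "des_missing"))
  pn <- vals[[which(els == "pop_number")]]
  expect_equal(pn$numeric, 88)
  expect_equal(substr(txt, pn$start + 1, pn$end), pn$value)
  expect_equal(rules_only_extract("", rs), list())
  # paraphrases outside the pattern inventory are missed (recall deficit)
  expect_length(rules_only_extract("入组者年龄介于18至65岁之间。", rs), 0L)
})

test_that("gold spans of rule-covered templates match their covering rule", {
  bank <- load_template_bank()
  rs <- starter_ruleset()
  corp <- generate_corpus(generator_config(n_docs = 25, seed = 99,
                                           ocr_noise_rate = 0))
  rule_of <- setNames(rs$pattern, rs$rule_id)
  covered <- unlist(lapply(bank$elements, function(e) {
    vapply(e$templates, function(t) !is.null(t$rule), logical(1))
  }))
  expect_true(any(covered) && !all(covered)) # bank mixes both kinds
  for (doc in corp$documents) {
    for (j in seq_len(nrow(doc$spans))) {
      s <- doc$spans[j, ]
      rules <- rs[rs$element == s$element & rs$action != "judge", ]
      hit <- any(vapply(rules$pattern, grepl, logical(1), x = s$text,
                        perl = TRUE))
      if (s$element %in% c("pop_number", "out_shedding", "des_missing")) {
        expect_true(hit) # D-level templates are fully rule-covered
      }
    }
  }
})

test_that("hybrid extraction is deterministic and records survive JSON I/O", {
  corp <- generate_corpus(generator_config(n_docs = 4, seed = 5))
  sch <- corp$schema
  m <- crf_labeler(corp$documents, sch, epochs = 2, seed = 1,
                   embed_dim = 8, hidden_dim = 8)
  rs <- starter_ruleset()
  r1 <- hybrid_extract(corp$documents[[1]], m, rs)
  r2 <- hybrid_extract(corp$documents[[1]], m, rs)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_picos_records(list(r1), p1)
  write_picos_records(list(r2), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_picos_records(p1)
  expect_equal(back[[1]]$doc_id, r1$doc_id)
  expect_equal(lengths(back[[1]]$elements), lengths(r1$elements))
  # empty prediction -> empty record
  empty <- picos_record("nil", list(), "model+rule")
  expect_equal(sum(lengths(empty$elements)), 0L)
})

test_that("parse_numeric handles Arabic digits and simple Chinese numerals", {
  expect_equal(parse_numeric("120"), 120)
  expect_equal(parse_numeric("45.5"), 45.5)
  expect_equal(parse_numeric("六十"), 60)
  expect_equal(parse_numeric("十五"), 15)
  expect_equal(parse_numeric("十"), 10)
  expect_equal(parse_numeric("一百二十三"), 123)
  expect_equal(parse_numeric("二百"), 200)
  expect_equal(parse_numeric("一二〇"), 120)
  expect_equal(parse_numeric("三"), 3)
  expect_true(is.na(parse_numeric("约百余")))
  expect_true(is.na(parse_numeric("abc")))
  expect_true(is.na(parse_numeric("")))
  expect_true(is.na(parse_numeric(NA_character_)))
})
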