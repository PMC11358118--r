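# Seeded generator of synthetic annotated RCT paragraphs. Documents are
# built from a Chinese template bank: per element, one evidence sentence is
# rendered from a typed-slot template (numbers, age ranges, institution
# names, therapy phrases, criteria sentences); distractor sentences —
# including "trap" sentences that superficially match a starter rule but
# carry no annotation — are interleaved and the order shuffled. Three RNG
# streams (structure, slots, noise) derive from the master seed so changing
# the noise rate does not reshuffle document structure.

OCR_CONFUSION <- chars_of("曰日末未土士千干己已人入大太目自口回王玉") # lookalikes

make_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    get(".Random.seed", envir = ge)
  } else NULL
  set.seed(seed)
  e$state <- get(".Random.seed", envir = ge)
  if (is.null(old)) rm(".Random.seed", envir = ge)
  else assign(".Random.seed", old, envir = ge)
  e
}

with_stream <- function(stream, expr) {
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    get(".Random.seed", envir = ge)
  } else NULL
  assign(".Random.seed", stream$state, envir = ge)
  on.exit({
    stream$state <- get(".Random.seed", envir = ge)
    if (is.null(old)) rm(".Random.seed", envir = ge)
    else assign(".Random.seed", old, envir = ge)
  })
  expr
}

num_to_zh <- function(n) { # unit style, 1..99
  d <- names(CN_DIGITS)
  if (n < 10) return(d[n + 1L])
  tens <- n %/% 10; ones <- n %% 10
  paste0(if (tens > 1) d[tens + 1L] else "", CN_TEN,
         if (ones > 0) d[ones + 1L] else "")
}

#' Load a template bank
#'
#' @param path YAML file; `NULL` loads the built-in Chinese bank,
#'   `"ascii"` the ASCII-transliterated one.
#' @return a `template_bank` list (slots, elements, distractors, doc_id
#'   pools).
#' @export
load_template_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "template_bank.yaml", package = "picosminer")
  } else if (identical(path, "ascii")) {
    path <- system.file("extdata", "template_bank_ascii.yaml",
                        package = "picosminer")
  }
  bank <- yaml::read_yaml(path)
  for (f in c("slots", "elements", "distractors")) {
    if (is.null(bank[[f]])) stop("template bank missing section '", f, "'")
  }
  structure(bank, class = "template_bank")
}

#' Generator configuration
#'
#' Defaults define the reference synthetic study conditions: every element
#' present in 90% of documents, four distractor sentences per document, a
#' 1% OCR-like character substitution rate outside gold spans, and
#' boundary-redundancy parameters (probability 0.3, up to 4 trailing
#' characters) used when perturbed prediction sets are derived from gold.
#'
#' @param n_docs number of documents.
#' @param seed master seed; structure, slot and noise streams derive from it.
#' @param include_prob scalar or per-element named vector of inclusion
#'   probabilities.
#' @param distractor_rate distractor sentences per document.
#' @param ocr_noise_rate per-character substitution probability outside gold
#'   spans.
#' @param redundancy_rate,k_max span-extension probability and maximum
#'   trailing length for [inject_redundancy()].
#' @param template_bank `NULL` (built-in), `"ascii"`, a path, or a loaded
#'   bank.
#' @param max_len segment length limit.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_docs, seed = 42L, include_prob = 0.9,
                             distractor_rate = 4L, ocr_noise_rate = 0.01,
                             redundancy_rate = 0.3, k_max = 4L,
                             template_bank = NULL, max_len = 128L) {
  stopifnot(n_docs >= 0, all(include_prob >= 0), all(include_prob <= 1),
            ocr_noise_rate >= 0, ocr_noise_rate <= 1,
            redundancy_rate >= 0, redundancy_rate <= 1, k_max >= 1)
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 include_prob = include_prob,
                 distractor_rate = as.integer(distractor_rate),
                 ocr_noise_rate = ocr_noise_rate,
                 redundancy_rate = redundancy_rate, k_max = as.integer(k_max),
                 template_bank = template_bank, max_len = as.integer(max_len)),
            class = "generator_config")
}

render_slots <- function(template, slot_defs, slot_stream) {
  slot_names <- unique(regmatches(template,
                                  gregexpr("\\{[a-z0-9_]+\\}", template))[[1]])
  slot_names <- gsub("[{}]", "", slot_names)
  vals <- list()
  for (s in slot_names) {
    def <- slot_defs[[s]]
    if (is.null(def)) stop("template references undefined slot '", s, "'")
    vals[[s]] <- with_stream(slot_stream, {
      if (def$type == "int") {
        v <- sample(def$min:def$max, 1L)
        zh <- !is.null(def$zh_prob) && runif(1) < def$zh_prob
        list(numeric = v, text = if (zh) num_to_zh(v) else as.character(v))
      } else if (def$type == "choice") {
        list(numeric = NA_real_, text = sample(unlist(def$options), 1L))
      } else stop("unknown slot type '", def$type, "'")
    })
  }
  vals
}

fill_template <- function(template, vals) {
  for (s in names(vals)) {
    template <- gsub(paste0("{", s, "}"), vals[[s]]$text, template,
                     fixed = TRUE)
  }
  template
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the config seed. Every gold span's offsets address
#' its rendered evidence value exactly; documents interleave evidence and
#' distractor sentences; gold annotations survive OCR noise untouched
#' (substitutions apply outside gold spans only).
#'
#' @param config a [generator_config()].
#' @param registry active `element_registry`.
#' @return a `picos_corpus`: list with `documents` (gold-tagged
#'   `picos_document`s), `records` (gold `picos_record`s), `schema`, and
#'   `config`.
#' @export
generate_corpus <- function(config, registry = element_registry()) {
  stopifnot(inherits(config, "generator_config"))
  bank <- if (inherits(config$template_bank, "template_bank")) {
    config$template_bank
  } else load_template_bank(config$template_bank)
  missing_el <- setdiff(registry$id, names(bank$elements))
  inc <- config$include_prob
  if (!is.null(names(inc))) {
    missing_el <- setdiff(names(inc)[inc > 0], names(bank$elements))
  }
  if (length(missing_el)) {
    stop("template bank missing element(s): ",
         paste(missing_el, collapse = ", "))
  }
  schema <- tag_schema(registry)
  inc_prob <- if (is.null(names(inc))) setNames(rep(inc[1], nrow(registry)),
                                                registry$id)
              else setNames(inc[registry$id], registry$id)

  s_struct <- make_stream(config$seed)
  s_slots <- make_stream(config$seed + 10007L)
  s_noise <- make_stream(config$seed + 20011L)

  documents <- list()
  records <- list()
  for (d in seq_len(config$n_docs)) {
    sentences <- list() # each: list(text, gold=list(element, gold_text, numeric))
    for (e in registry$id) {
      take <- with_stream(s_struct, runif(1) < inc_prob[[e]])
      if (!take) next
      tpls <- bank$elements[[e]]$templates
      tpl <- tpls[[with_stream(s_struct, sample.int(length(tpls), 1L))]]
      vals <- render_slots(tpl$sentence, bank$slots, s_slots)
      text <- fill_template(tpl$sentence, vals)
      gold_text <- fill_template(tpl$gold, vals)
      numeric <- NA_real_
      if (!is.null(tpl$numeric_slot)) numeric <- vals[[tpl$numeric_slot]]$numeric
      sentences <- c(sentences, list(list(
        text = text, element = e, gold_text = gold_text, numeric = numeric)))
    }
    n_dis <- config$distractor_rate
    if (n_dis > 0L) {
      picks <- with_stream(s_struct,
                           sample.int(length(bank$distractors), n_dis,
                                      replace = TRUE))
      for (p in picks) {
        tpl <- bank$distractors[[p]]
        vals <- render_slots(tpl$sentence, bank$slots, s_slots)
        sentences <- c(sentences, list(list(
          text = fill_template(tpl$sentence, vals), element = NA_character_)))
      }
    }
    if (length(sentences) > 1L) {
      ord <- with_stream(s_struct, sample.int(length(sentences)))
      sentences <- sentences[ord]
    }
    texts <- vapply(sentences, `[[`, character(1), "text")
    offs <- c(0L, cumsum(nchar(texts)))
    spans <- entity_spans()
    numerics <- numeric(0)
    for (i in seq_along(sentences)) {
      s <- sentences[[i]]
      if (is.na(s$element)) next
      rel <- regexpr(s$gold_text, s$text, fixed = TRUE)
      if (rel[1] == -1L) stop("gold text not found in rendered sentence: ",
                              s$gold_text)
      st <- offs[i] + rel[1] - 1L
      spans <- rbind(spans, entity_spans(s$element, st,
                                         st + nchar(s$gold_text),
                                         text = s$gold_text,
                                         level = element_level(registry,
                                                               s$element)))
      numerics <- c(numerics, s$numeric)
    }
    text <- paste(texts, collapse = "")
    if (config$ocr_noise_rate > 0 && nchar(text) > 0L) {
      text <- with_stream(s_noise,
                          noise_text(text, spans, config$ocr_noise_rate))
      if (nrow(spans)) {
        spans$text <- slice_text(text, spans$start, spans$end)
      }
    }
    year <- with_stream(s_struct, sample(2005:2023, 1L))
    author <- bank$doc_id$authors[[with_stream(
      s_struct, sample.int(length(bank$doc_id$authors), 1L))]]
    title <- bank$doc_id$titles[[with_stream(
      s_struct, sample.int(length(bank$doc_id$titles), 1L))]]
    doc_id <- sprintf("%04d_%d_%s_%s", d, year, author, title)
    documents[[d]] <- picos_document(doc_id, text, spans = spans,
                                     schema = schema,
                                     max_len = config$max_len)
    vals <- lapply(seq_len(nrow(spans)), function(i) {
      list(element = spans$element[i], value = spans$text[i],
           numeric = numerics[i], start = spans$start[i], end = spans$end[i],
           rule_id = "gold", raw_start = spans$start[i],
           raw_end = spans$end[i])
    })
    records[[d]] <- picos_record(doc_id, vals, "gold", registry)
  }
  structure(list(documents = documents, records = records, schema = schema,
                 config = config),
            class = "picos_corpus")
}

#' @export
print.picos_corpus <- function(x, ...) {
  n_spans <- sum(vapply(x$documents, function(d) {
    if (is.null(d$spans)) 0L else nrow(d$spans)
  }, integer(1)))
  cat("<picos_corpus> ", length(x$documents), " document(s), ",
      n_spans, " gold span(s), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

noise_text <- function(text, spans, rate) {
  ch <- chars_of(text)
  protected <- rep(FALSE, length(ch))
  for (i in seq_len(nrow(spans))) {
    protected[(spans$start[i] + 1L):spans$end[i]] <- TRUE
  }
  hit <- !protected & runif(length(ch)) < rate
  for (i in which(hit)) {
    pool <- setdiff(OCR_CONFUSION, ch[i])
    ch[i] <- pool[sample.int(length(pool), 1L)]
  }
  paste(ch, collapse = "")
}

#' Inject OCR-like character noise into a document
#'
#' Each character outside a gold span is independently replaced by a
#' character from a fixed confusion alphabet with probability `rate`.
#' Substitutions are one-to-one, so gold offsets are preserved.
#'
#' @param document a `picos_document` (gold spans, if any, are protected).
#' @param rate substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param schema `tag_schema` used to rebuild segment tags.
#' @return a new `picos_document`.
#' @export
inject_ocr_noise <- function(document, rate, seed,
                             schema = tag_schema(element_registry())) {
  stopifnot(rate >= 0, rate <= 1)
  spans <- if (is.null(document$spans)) entity_spans() else document$spans
  s <- make_stream(seed)
  text <- with_stream(s, noise_text(document$text, spans, rate))
  if (nrow(spans)) spans$text <- slice_text(text, spans$start, spans$end)
  picos_document(document$doc_id, text,
                 spans = if (is.null(document$spans)) NULL else spans,
                 schema = schema)
}

#' Derive a boundary-redundant prediction set from gold spans
#'
#' Each gold span is independently selected with probability `rate` and
#' extended rightward by 1..`k_max` characters (clipped at the text end),
#' emulating the trailing-character redundancy of model output. Strict
#' matching fails on extended spans while relaxed matching accepts them
#' when within tolerance. The logical attribute `"extended"` records which
#' spans actually grew.
#'
#' @param spans gold `entity_spans()`.
#' @param text_len document length in characters.
#' @param rate extension probability.
#' @param k_max maximum extension.
#' @param seed RNG seed.
#' @return perturbed `entity_spans()` with attribute `"extended"`.
#' @export
inject_redundancy <- function(spans, text_len, rate, k_max, seed) {
  stopifnot(k_max >= 1, rate >= 0, rate <= 1)
  s <- make_stream(seed)
  out <- spans
  extended <- rep(FALSE, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    sel <- with_stream(s, runif(1) < rate)
    k <- with_stream(s, sample.int(k_max, 1L))
    if (!sel) next
    new_end <- min(spans$end[i] + k, text_len)
    if (new_end > out$end[i]) {
      out$end[i] <- new_end
      extended[i] <- TRUE
    }
  }
  attr(out, "extended") <- extended
  out
}
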