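# Rule-set formalism: PATTERN = {Pattern1, Pattern2, ...} — ordered,
# element-keyed regular-expression rules refining coarse labeler spans into
# fine-grained evidence values. Actions:
#   match — first match wins; the full match is the refined value;
#   judge — a boolean gate: a span whose text fails the judge pattern for
#           its element is vetoed (dropped); judge never re-classifies;
#   split — one refined value per named capture group.
# Spans no rule claims pass through unchanged with rule_id = "fallback".

#' Compile a rule set
#'
#' @param x path to a UTF-8 JSON file (array of objects with fields
#'   `rule_id`, `element`, `pattern`, `action`, `priority`) or an
#'   equivalent list of lists.
#' @param registry `element_registry` the rules must reference.
#' @return a `ruleset` object: data.frame of rules ordered by
#'   (element, priority, rule_id).
#' @export
compile_ruleset <- function(x, registry = element_registry()) {
  rules <- if (is.character(x) && length(x) == 1L) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else x
  if (!length(rules)) stop("empty ruleset")
  df <- do.call(rbind, lapply(rules, function(r) {
    for (f in c("rule_id", "element", "pattern", "action")) {
      if (is.null(r[[f]])) stop("rule missing field '", f, "'")
    }
    data.frame(rule_id = r$rule_id, element = r$element, pattern = r$pattern,
               action = r$action,
               priority = if (is.null(r$priority)) 100L else as.integer(r$priority),
               stringsAsFactors = FALSE)
  }))
  dup <- df$rule_id[duplicated(df$rule_id)]
  if (length(dup)) stop("duplicate rule_id(s): ", paste(unique(dup), collapse = ", "))
  bad_el <- setdiff(df$element, registry$id)
  if (length(bad_el)) stop("rule element(s) not in registry: ",
                           paste(bad_el, collapse = ", "))
  bad_act <- setdiff(df$action, c("match", "judge", "split"))
  if (length(bad_act)) stop("unknown action(s): ", paste(bad_act, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ regexpr(df$pattern[i], "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("rule '", df$rule_id[i], "': pattern does not compile: ",
                  df$pattern[i])
    if (df$action[i] == "split" && !grepl("\\(\\?P?<", df$pattern[i])) {
      stop("rule '", df$rule_id[i], "': split action requires >= 1 named group")
    }
  }
  df <- df[order(match(df$element, registry$id), df$priority, df$rule_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ruleset", "data.frame"), registry = registry)
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset> ", nrow(x), " rule(s) over ",
      length(unique(x$element)), " element(s)\n", sep = "")
  print.data.frame(x[, c("rule_id", "element", "action", "priority")],
                   row.names = FALSE)
  invisible(x)
}

# First regex match with named-capture bookkeeping; offsets are 0-based
# half-open character offsets into `text`. Returns NULL if no match.
regex_first_match <- function(pattern, text) {
  m <- regexpr(pattern, text, perl = TRUE)
  if (m[1] == -1L) return(NULL)
  start <- m[1] - 1L
  end <- start + attr(m, "match.length")
  groups <- NULL
  cn <- attr(m, "capture.names")
  if (!is.null(cn)) {
    cs <- attr(m, "capture.start")[1, ]
    cl <- attr(m, "capture.length")[1, ]
    keep <- nzchar(cn) & cs > 0L
    if (any(keep)) {
      groups <- data.frame(name = cn[keep], start = cs[keep] - 1L,
                           end = cs[keep] - 1L + cl[keep],
                           stringsAsFactors = FALSE)
    }
  }
  list(start = start, end = end, groups = groups)
}

refined_value <- function(element, value, start, end, rule_id, raw_span,
                          level) {
  numeric <- if (identical(level, "D")) parse_numeric(value) else NA_real_
  list(element = element, value = value, numeric = numeric,
       start = as.integer(start), end = as.integer(end), rule_id = rule_id,
       raw_start = as.integer(raw_span$start), raw_end = as.integer(raw_span$end))
}

#' Refine one predicted span through the rule set
#'
#' Rules for the span's element are tried in (priority, rule_id) order.
#' A failing `judge` rule vetoes the span (empty result). The first
#' matching `match` rule emits the full match as the refined value; the
#' first matching `split` rule emits one value per captured named group.
#' If no rule matches, the raw span passes through with
#' `rule_id = "fallback"`. For D-level elements the numeric reading is
#' [parse_numeric()] of the first named capture when the winning rule
#' declares one, else of the value itself.
#'
#' @param span one-row `entity_spans()` table (document coordinates,
#'   `text` filled).
#' @param ruleset a compiled `ruleset`.
#' @return list of refined values (possibly empty after a veto), each with
#'   fields element, value, numeric, start, end, rule_id, raw_start,
#'   raw_end.
#' @export
apply_rules_to_span <- function(span, ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  registry <- attr(ruleset, "registry")
  if (is.data.frame(span)) span <- as.list(span[1, ])
  if (!(span$element %in% registry$id)) {
    stop("span element not in registry: ", span$element)
  }
  level <- element_level(registry, span$element)
  rules <- ruleset[ruleset$element == span$element, , drop = FALSE]
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (r$action == "judge") {
      if (!grepl(r$pattern, span$text, perl = TRUE)) return(list()) # veto
      next
    }
    m <- regex_first_match(r$pattern, span$text)
    if (is.null(m)) next
    if (r$action == "match") {
      value <- substr(span$text, m$start + 1L, m$end)
      out <- refined_value(span$element, value, span$start + m$start,
                           span$start + m$end, r$rule_id, span, level)
      if (identical(level, "D") && !is.null(m$groups) && nrow(m$groups)) {
        g1 <- substr(span$text, m$groups$start[1] + 1L, m$groups$end[1])
        out$numeric <- parse_numeric(g1)
      }
      return(list(out))
    }
    if (r$action == "split") {
      if (is.null(m$groups) || !nrow(m$groups)) next
      return(lapply(seq_len(nrow(m$groups)), function(j) {
        g <- m$groups[j, ]
        refined_value(span$element, substr(span$text, g$start + 1L, g$end),
                      span$start + g$start, span$start + g$end,
                      r$rule_id, span, level)
      }))
    }
  }
  list(refined_value(span$element, span$text, span$start, span$end,
                     "fallback", span, level))
}

sentence_offsets <- function(text) {
  ch <- chars_of(text)
  if (!length(ch)) return(data.frame(start = integer(0), end = integer(0)))
  ends <- which(ch %in% SENT_PUNCT)
  bounds <- unique(c(0L, ends, length(ch)))
  starts <- bounds[-length(bounds)]
  stops <- bounds[-1L]
  keep <- stops > starts
  data.frame(start = starts[keep], end = stops[keep])
}

#' Rule-only extraction over raw text
#'
#' The baseline mode that skips the neural labeler: the document is split
#' into sentences (on the sentence-final marks), and for every element the
#' first rule (in priority order) whose pattern fires in a sentence emits
#' its values there. `judge` rules are span gates and do not participate.
#'
#' @param text document text.
#' @param ruleset compiled `ruleset`.
#' @return list of refined values in document coordinates.
#' @export
rules_only_extract <- function(text, ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  registry <- attr(ruleset, "registry")
  sents <- sentence_offsets(text)
  out <- list()
  for (si in seq_len(nrow(sents))) {
    s0 <- sents$start[si]
    sent <- substr(text, s0 + 1L, sents$end[si])
    for (e in unique(ruleset$element)) {
      level <- element_level(registry, e)
      rules <- ruleset[ruleset$element == e & ruleset$action != "judge", ,
                       drop = FALSE]
      for (i in seq_len(nrow(rules))) {
        r <- rules[i, ]
        m <- regex_first_match(r$pattern, sent)
        if (is.null(m)) next
        pseudo <- list(element = e, start = s0, end = sents$end[si], text = sent)
        if (r$action == "match") {
          value <- substr(sent, m$start + 1L, m$end)
          rv <- refined_value(e, value, s0 + m$start, s0 + m$end,
                              r$rule_id, pseudo, level)
          if (identical(level, "D") && !is.null(m$groups) && nrow(m$groups)) {
            g1 <- substr(sent, m$groups$start[1] + 1L, m$groups$end[1])
            rv$numeric <- parse_numeric(g1)
          }
          out <- c(out, list(rv))
        } else { # split
          if (is.null(m$groups) || !nrow(m$groups)) next
          out <- c(out, lapply(seq_len(nrow(m$groups)), function(j) {
            g <- m$groups[j, ]
            refined_value(e, substr(sent, g$start + 1L, g$end),
                          s0 + g$start, s0 + g$end, r$rule_id, pseudo, level)
          }))
        }
        break # first-match-wins per element per sentence
      }
    }
  }
  out
}

#' Per-document structured extraction record
#'
#' @param doc_id document id.
#' @param values list of refined values.
#' @param provenance `"model+rule"`, `"model-only"`, `"rule-only"`, or
#'   `"gold"`.
#' @param registry active registry (restricts elements).
#' @return a `picos_record`.
#' @export
picos_record <- function(doc_id, values, provenance,
                         registry = element_registry()) {
  bad <- setdiff(vapply(values, `[[`, character(1), "element"), registry$id)
  if (length(bad)) stop("refined value element(s) not in registry: ",
                        paste(unique(bad), collapse = ", "))
  elements <- setNames(vector("list", nrow(registry)), registry$id)
  for (v in values) elements[[v$element]] <- c(elements[[v$element]], list(v))
  structure(list(doc_id = doc_id, elements = elements,
                 provenance = provenance),
            class = "picos_record")
}

#' @export
print.picos_record <- function(x, ...) {
  n <- sum(lengths(x$elements))
  cat("<picos_record> ", x$doc_id, " (", x$provenance, "): ", n,
      " value(s)\n", sep = "")
  for (e in names(x$elements)) {
    for (v in x$elements[[e]]) {
      cat(sprintf("  %-14s [%d,%d) %s%s (%s)\n", e, v$start, v$end, v$value,
                  if (!is.na(v$numeric)) paste0(" = ", v$numeric) else "",
                  v$rule_id))
    }
  }
  invisible(x)
}

record_spans <- function(record) {
  vals <- unlist(record$elements, recursive = FALSE, use.names = FALSE)
  if (!length(vals)) return(entity_spans())
  entity_spans(element = vapply(vals, `[[`, character(1), "element"),
               start = vapply(vals, `[[`, integer(1), "start"),
               end = vapply(vals, `[[`, integer(1), "end"),
               text = vapply(vals, `[[`, character(1), "value"))
}

#' Hybrid neural + rule extraction for one document
#'
#' The labeler proposes coarse spans (anchoring the rule search to ranges
#' it has already located), then each span is refined through the rule set;
#' the refined values are assembled into a `picos_record` with provenance
#' `"model+rule"`.
#'
#' @param document a `picos_document`.
#' @param model a fitted `crf_labeler`.
#' @param ruleset compiled `ruleset` (or `NULL` for model-only output).
#' @return a `picos_record`.
#' @export
hybrid_extract <- function(document, model, ruleset = NULL) {
  stopifnot(inherits(document, "picos_document"),
            inherits(model, "crf_labeler"))
  registry <- model$schema$registry
  spans <- predict(model, document)[[1]]
  if (is.null(ruleset)) {
    vals <- lapply(seq_len(nrow(spans)), function(i) {
      s <- spans[i, ]
      refined_value(s$element, s$text, s$start, s$end, "model",
                    list(start = s$start, end = s$end),
                    element_level(registry, s$element))
    })
    return(picos_record(document$doc_id, vals, "model-only", registry))
  }
  vals <- list()
  for (i in seq_len(nrow(spans))) {
    vals <- c(vals, apply_rules_to_span(spans[i, ], ruleset))
  }
  picos_record(document$doc_id, vals, "model+rule", registry)
}

#' Read or write extraction records as JSON
#'
#' One object per document:
#' `{"doc_id": ..., "provenance": ..., "elements": {id: [{"value",
#' "numeric", "start", "end", "rule_id"}]}}`. Output is byte-deterministic
#' for fixed input.
#'
#' @param records list of `picos_record`.
#' @param path output path.
#' @export
write_picos_records <- function(records, path) {
  body <- lapply(records, function(r) {
    els <- r$elements[lengths(r$elements) > 0L]
    list(doc_id = r$doc_id, provenance = r$provenance,
         elements = lapply(els, function(vs) {
           lapply(vs, function(v) {
             list(value = v$value,
                  numeric = if (is.na(v$numeric)) NULL else v$numeric,
                  start = v$start, end = v$end, rule_id = v$rule_id)
           })
         }))
  })
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(enc2utf8(json), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_picos_records
#' @param registry registry used to re-validate elements.
#' @export
read_picos_records <- function(path, registry = element_registry()) {
  body <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(body, function(r) {
    vals <- list()
    for (e in names(r$elements)) {
      level <- element_level(registry, e)
      for (v in r$elements[[e]]) {
        vals <- c(vals, list(list(
          element = e, value = v$value,
          numeric = if (is.null(v$numeric)) NA_real_ else as.numeric(v$numeric),
          start = as.integer(v$start), end = as.integer(v$end),
          rule_id = v$rule_id, raw_start = NA_integer_, raw_end = NA_integer_)))
      }
    }
    picos_record(r$doc_id, vals, r$provenance, registry)
  })
}

CN_DIGITS <- c("〇" = 0, "一" = 1, "二" = 2, "三" = 3,
               "四" = 4, "五" = 5, "六" = 6, "七" = 7,
               "八" = 8, "九" = 9) # 〇一二三四五六七八九
CN_TEN <- "十"      # 十
CN_HUNDRED <- "百"  # 百

#' Parse a numeric evidence value
#'
#' Accepts Arabic numerals (optionally with a decimal point) and simple
#' Chinese numerals built from 〇一二三四五六七八九十百 — either digit
#' style (一二〇 = 120) or unit style (一百二十 = 120, 六十 = 60,
#' 十五 = 15). Returns `NA` for anything else; never raises.
#'
#' @param value character scalar.
#' @return numeric scalar or `NA_real_`.
#' @examples
#' parse_numeric("120")
#' parse_numeric("六十") # 60
#' @export
parse_numeric <- function(value) {
  if (is.null(value) || length(value) != 1L || is.na(value)) return(NA_real_)
  v <- gsub("^\\s+|\\s+$", "", value)
  if (!nzchar(v)) return(NA_real_)
  if (grepl("^[0-9]+(\\.[0-9]+)?$", v)) return(as.numeric(v))
  ch <- chars_of(v)
  if (!all(ch %in% c(names(CN_DIGITS), CN_TEN, CN_HUNDRED))) return(NA_real_)
  if (all(ch %in% names(CN_DIGITS))) { # digit style
    return(as.numeric(paste(CN_DIGITS[ch], collapse = "")))
  }
  total <- 0; cur <- NA_real_
  for (c in ch) {
    if (c %in% names(CN_DIGITS)) {
      if (!is.na(cur)) return(NA_real_) # two digits without a unit
      cur <- CN_DIGITS[[c]]
    } else if (c == CN_TEN) {
      total <- total + (if (is.na(cur)) 1 else cur) * 10
      cur <- NA_real_
    } else { # 百
      total <- total + (if (is.na(cur)) 1 else cur) * 100
      cur <- NA_real_
    }
  }
  total + (if (is.na(cur)) 0 else cur)
}
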