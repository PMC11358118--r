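#' Confusion counts and entity-level precision/recall/F1
#'
#' Entity-level scoring uses TP/FP/FN tallies (TN is carried for
#' completeness but unused by span metrics):
#' \deqn{Recall = TP / (TP + FN)}
#' \deqn{Precision = TP / (TP + FP)}
#' \deqn{F1 = 2 \cdot Precision \cdot Recall / (Precision + Recall)}
#' A zero denominator yields 0 and sets the `degenerate` flag.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return `confusion_counts()`: a `confusion_counts` object.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param counts a `confusion_counts` object.
#' @return `compute_prf()`: list with `precision`, `recall`, `f1` in
#'   `[0, 1]` and a logical `degenerate` flag.
#' @examples
#' compute_prf(confusion_counts(tp = 2, fp = 1, fn = 1)) # 2/3 across the board
#' @export
compute_prf <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  degen <- FALSE
  p <- if (counts$tp + counts$fp == 0L) { degen <- TRUE; 0 }
       else counts$tp / (counts$tp + counts$fp)
  r <- if (counts$tp + counts$fn == 0L) { degen <- TRUE; 0 }
       else counts$tp / (counts$tp + counts$fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, degenerate = degen)
}

#' Span matching configuration
#'
#' `strict` requires identical (element, start, end). `relaxed` accepts a
#' prediction whose interval contains the gold interval with the same
#' element, provided the surplus length does not exceed
#' `max(tol_abs, tol_frac * |gold|)` — the operational form of "trailing
#' redundant characters do not change the reading" of an evidence value.
#'
#' @param mode `"strict"` or `"relaxed"`.
#' @param tol_abs absolute surplus tolerance in characters (default 10).
#' @param tol_frac surplus tolerance as a fraction of the gold length
#'   (default 0.5).
#' @return a `match_config` object.
#' @export
match_config <- function(mode = c("strict", "relaxed"), tol_abs = 10L,
                         tol_frac = 0.5) {
  mode <- match.arg(mode)
  stopifnot(tol_abs >= 0, tol_frac >= 0)
  structure(list(mode = mode, tol_abs = as.integer(tol_abs),
                 tol_frac = tol_frac),
            class = "match_config")
}

span_matches <- function(g, p, config) {
  if (g$element != p$element) return(FALSE)
  if (config$mode == "strict") {
    return(g$start == p$start && g$end == p$end)
  }
  if (!(p$start <= g$start && p$end >= g$end)) return(FALSE) # containment
  surplus <- (p$end - p$start) - (g$end - g$start)
  surplus <= max(config$tol_abs, config$tol_frac * (g$end - g$start))
}

#' Match predicted against gold spans
#'
#' Greedy one-to-one matching in document order: predictions are visited by
#' start offset and each claims the first unmatched gold span it matches
#' under `config`. Matched pairs count TP, unmatched predictions FP,
#' unmatched gold FN.
#'
#' @param gold,pred `entity_spans()` tables for one document.
#' @param config a [match_config()].
#' @return `confusion_counts`.
#' @export
match_spans <- function(gold, pred, config = match_config("strict")) {
  stopifnot(inherits(config, "match_config"))
  if (is.null(gold)) gold <- entity_spans()
  if (is.null(pred)) pred <- entity_spans()
  gold <- gold[order(gold$start, gold$end), , drop = FALSE]
  pred <- pred[order(pred$start, pred$end), , drop = FALSE]
  taken <- rep(FALSE, nrow(gold))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (!taken[j] && span_matches(gold[j, ], pred[i, ], config)) {
        taken[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  confusion_counts(tp = tp, fp = nrow(pred) - tp, fn = sum(!taken))
}

#' Score extraction output against gold documents
#'
#' Pools TP/FP/FN per element across documents and reports per-element
#' precision/recall/F1 plus the micro-average (all counts pooled), in
#' registry order.
#'
#' @param gold_docs list of `picos_document` carrying gold spans (or a named
#'   list of `entity_spans()` tables keyed by doc_id).
#' @param pred_records list of `picos_record` (see [hybrid_extract()]) or a
#'   named list of `entity_spans()` tables.
#' @param config a [match_config()].
#' @param registry the `element_registry` ordering the report; defaults to
#'   the registry of the first gold document's schema when available, else
#'   the default registry.
#' @return list with `per_element` (data.frame element/tp/fp/fn/precision/
#'   recall/f1) and `micro` (PRF list), plus the `mode` used.
#' @export
evaluate_extraction <- function(gold_docs, pred_records,
                                config = match_config("strict"),
                                registry = element_registry()) {
  gold_spans <- spans_by_doc(gold_docs)
  pred_spans <- spans_by_doc(pred_records)
  missing_ids <- setdiff(names(pred_spans), names(gold_spans))
  if (length(missing_ids)) {
    stop("prediction doc_id(s) absent from gold: ",
         paste(missing_ids, collapse = ", "))
  }
  els <- registry$id
  counts <- matrix(0L, nrow = length(els), ncol = 3L,
                   dimnames = list(els, c("tp", "fp", "fn")))
  for (id in names(gold_spans)) {
    g <- gold_spans[[id]]
    p <- pred_spans[[id]]
    if (is.null(p)) p <- entity_spans()
    for (e in els) {
      cc <- match_spans(g[g$element == e, , drop = FALSE],
                        p[p$element == e, , drop = FALSE], config)
      counts[e, ] <- counts[e, ] + c(cc$tp, cc$fp, cc$fn)
    }
  }
  per_element <- do.call(rbind, lapply(els, function(e) {
    prf <- compute_prf(confusion_counts(counts[e, "tp"], counts[e, "fp"],
                                        counts[e, "fn"]))
    data.frame(element = e, tp = counts[e, "tp"], fp = counts[e, "fp"],
               fn = counts[e, "fn"], precision = prf$precision,
               recall = prf$recall, f1 = prf$f1, stringsAsFactors = FALSE)
  }))
  rownames(per_element) <- NULL
  tot <- colSums(counts)
  micro <- compute_prf(confusion_counts(tot["tp"], tot["fp"], tot["fn"]))
  list(mode = config$mode, per_element = per_element, micro = micro)
}

spans_by_doc <- function(x) {
  if (is.null(x)) return(list())
  out <- list()
  for (i in seq_along(x)) {
    item <- x[[i]]
    if (inherits(item, "picos_document")) {
      out[[item$doc_id]] <- if (is.null(item$spans)) entity_spans() else item$spans
    } else if (inherits(item, "picos_record")) {
      out[[item$doc_id]] <- record_spans(item)
    } else if (is.data.frame(item)) {
      nm <- names(x)[i]
      if (is.null(nm) || !nzchar(nm)) stop("span tables must be named by doc_id")
      out[[nm]] <- item
    } else stop("cannot extract spans from object of class ",
                paste(class(item), collapse = "/"))
  }
  out
}

#' Aligned-text evaluation report
#'
#' @param result value of [evaluate_extraction()].
#' @return the lines of the table, invisibly (printed as a side effect).
#' @export
format_eval_report <- function(result) {
  lines <- c(sprintf("%-16s %5s %5s %5s %9s %7s %7s",
                     paste0("element (", result$mode, ")"),
                     "TP", "FP", "FN", "Precision", "Recall", "F1"))
  for (i in seq_len(nrow(result$per_element))) {
    r <- result$per_element[i, ]
    lines <- c(lines, sprintf("%-16s %5d %5d %5d %9.3f %7.3f %7.3f",
                              r$element, r$tp, r$fp, r$fn,
                              r$precision, r$recall, r$f1))
  }
  m <- result$micro
  lines <- c(lines, sprintf("%-16s %17s %9.3f %7.3f %7.3f", "micro", "",
                            m$precision, m$recall, m$f1))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two raters on a binary judgment
#' (e.g. "accurate" vs "ambiguous" annotation quality):
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the diagonal
#' proportion and \eqn{p_e} the agreement expected from the marginals.
#'
#' @param table 2x2 numeric matrix; rows = rater A, columns = rater B.
#' @return a `kappa_result` list: `p_o`, `p_e`, `kappa`, `n`.
#' @examples
#' cohens_kappa(matrix(c(1746, 56, 118, 504), 2, 2)) # kappa 0.806
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty agreement table")
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  if (p_e >= 1) {
    if (p_o == 1) {
      kappa <- 1
    } else {
      stop("expected agreement is 1 but observed agreement is not; ",
           "kappa undefined")
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (observed %.4f, expected %.4f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, as.integer(x$n)))
  invisible(x)
}

#' Agreement cell proportions of a 2x2 table
#'
#' Reports the two diagonal cells as percentages of the total: the fraction
#' of items both raters judged in the first category ("both accurate") and
#' in the second ("both ambiguous"), truncated to 2 decimals (the reporting
#' convention for these proportions).
#'
#' @inheritParams cohens_kappa
#' @return named numeric vector `c(both_first = ..., both_second = ...)`.
#' @export
agreement_proportions <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty agreement table")
  trunc2 <- function(x) floor(x * 100 + 1e-9) / 100
  c(both_first = trunc2(100 * table[1, 1] / n),
    both_second = trunc2(100 * table[2, 2] / n))
}
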