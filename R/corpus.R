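#' @useDynLib picosminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict runif setNames
#' @importFrom utils head modifyList
NULL

# Sentence-final punctuation used for preferred cut points and for the
# sentence scanner of the rules-only baseline.
SENT_PUNCT <- c("。", "；", "！", "？") # 。；！？

chars_of <- function(text) {
  if (nchar(text) == 0L) character(0) else strsplit(text, "", fixed = FALSE)[[1]]
}

#' Entity span table constructor
#'
#' Spans use 0-based half-open character (code point) offsets into the
#' document text, so `substr(text, start + 1, end)` recovers the surface
#' string.
#'
#' @param element character vector of element ids.
#' @param start,end integer vectors, 0-based half-open.
#' @param text optional surface strings.
#' @param level optional A/B/C/D levels.
#' @return data.frame with columns element, start, end, text, level.
#' @export
entity_spans <- function(element = character(), start = integer(),
                         end = integer(), text = NA_character_,
                         level = NA_character_) {
  n <- length(element)
  if (n == 0L) {
    text <- character(0)
    level <- character(0)
  }
  df <- data.frame(element = as.character(element),
                   start = as.integer(start), end = as.integer(end),
                   text = as.character(text), level = as.character(level),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0L | df$end <= df$start)) {
    stop("invalid span offsets: require 0 <= start < end")
  }
  df
}

slice_text <- function(text, start, end) {
  if (length(start) == 0L) return(character(0))
  substr(rep(text, length(start)), start + 1L, end)
}

#' Segment a document into model-sized pieces
#'
#' Cuts text into segments of at most `max_len` characters, preferring the
#' last sentence-final punctuation mark at or before the limit and falling
#' back to a hard cut. The segments partition the input exactly. When gold
#' `spans` are supplied, a cut that would fall strictly inside a span is
#' shifted back to the span start so annotated entities are never split
#' (unless a single span exceeds `max_len`, in which case the hard cut
#' stands).
#'
#' @param text UTF-8 string.
#' @param max_len maximum segment length in characters (default 128).
#' @param spans optional `entity_spans()` table of gold annotations.
#' @return character vector of segments; `character(0)` for empty input.
#' @export
segment_document <- function(text, max_len = 128L, spans = NULL) {
  stopifnot(is.character(text), length(text) == 1L, max_len >= 2L)
  ch <- chars_of(text)
  n <- length(ch)
  if (n == 0L) return(character(0))
  is_punct <- ch %in% SENT_PUNCT
  segs <- character(0)
  pos <- 0L # chars consumed (0-based cut position)
  while (pos < n) {
    if (n - pos <= max_len) {
      segs <- c(segs, paste(ch[(pos + 1L):n], collapse = ""))
      break
    }
    limit <- pos + max_len
    window <- which(is_punct[(pos + 1L):limit])
    cut <- if (length(window)) pos + window[length(window)] else limit
    if (!is.null(spans) && nrow(spans)) {
      inside <- spans$start < cut & spans$end > cut
      if (any(inside)) {
        s <- max(spans$start[inside])
        if (s > pos) cut <- s # else span longer than segment: hard cut stands
      }
    }
    segs <- c(segs, paste(ch[(pos + 1L):cut], collapse = ""))
    pos <- cut
  }
  segs
}

#' Convert spans to a BIO tag sequence
#'
#' @param spans `entity_spans()` table with offsets relative to the sequence
#'   being tagged (non-overlapping).
#' @param length sequence length in characters.
#' @param schema a `tag_schema`.
#' @return character vector of `length` tags.
#' @export
spans_to_tags <- function(spans, length, schema) {
  stopifnot(inherits(schema, "tag_schema"))
  tags <- rep("O", length)
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  unknown <- setdiff(spans$element, schema$registry$id)
  if (length(unknown)) stop("span element(s) not in schema: ",
                            paste(unknown, collapse = ", "))
  if (any(spans$start < 0L | spans$end > length)) {
    stop("span offsets outside [0, ", length, ")")
  }
  ord <- order(spans$start)
  s <- spans[ord, , drop = FALSE]
  if (nrow(s) > 1L) {
    prev_end <- s$end[-nrow(s)]
    nxt_start <- s$start[-1L]
    bad <- which(nxt_start < prev_end)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("overlapping spans: [%d,%d) '%s' and [%d,%d) '%s'",
                   s$start[i], s$end[i], s$element[i],
                   s$start[i + 1L], s$end[i + 1L], s$element[i + 1L]))
    }
  }
  for (i in seq_len(nrow(s))) {
    idx <- (s$start[i] + 1L):s$end[i]
    tags[idx] <- paste0("I-", s$element[i])
    tags[idx[1L]] <- paste0("B-", s$element[i])
  }
  tags
}

#' Recover entity spans from a BIO tag sequence
#'
#' Inverse of [spans_to_tags()] on valid sequences. An `I-` tag that opens an
#' entity (after `O`, after a different element, or at sequence start) is
#' conflated to `B-` and reported as a repair via a warning; the repaired
#' positions (1-based) are attached as attribute `"repairs"`.
#'
#' @param tags character vector of tags drawn from `schema`.
#' @param schema a `tag_schema`.
#' @param text optional text the tags annotate (fills the `text` column).
#' @param offset integer added to the 0-based offsets (maps segment-relative
#'   spans into document coordinates).
#' @return `entity_spans()` table.
#' @export
tags_to_spans <- function(tags, schema, text = NULL, offset = 0L) {
  stopifnot(inherits(schema, "tag_schema"))
  tag_index(schema, tags) # unknown tag -> error
  n <- length(tags)
  el <- character(0); st <- integer(0); en <- integer(0)
  repairs <- integer(0)
  cur_el <- NA_character_; cur_start <- NA_integer_
  close_cur <- function(i) {
    if (!is.na(cur_el)) {
      el <<- c(el, cur_el); st <<- c(st, cur_start); en <<- c(en, i - 1L)
    }
    cur_el <<- NA_character_
  }
  for (i in seq_len(n)) {
    t <- tags[i]
    if (t == "O") { close_cur(i); next }
    kind <- substr(t, 1L, 1L)
    e <- schema$element_of[[t]]
    if (kind == "B") {
      close_cur(i)
      cur_el <- e; cur_start <- i - 1L
    } else { # I-
      if (is.na(cur_el) || cur_el != e) {
        close_cur(i)
        repairs <- c(repairs, i)
        cur_el <- e; cur_start <- i - 1L
      }
    }
  }
  close_cur(n + 1L)
  if (length(repairs)) {
    warning("repaired ", length(repairs),
            " leading I-tag(s) to B at position(s) ",
            paste(repairs, collapse = ", "))
  }
  txt <- if (!is.null(text)) slice_text(text, st + offset, en + offset) else NA_character_
  out <- entity_spans(el, st + offset, en + offset, text = txt,
                      level = if (length(el)) element_level(schema$registry, el)
                              else NA_character_)
  attr(out, "repairs") <- repairs
  out
}

#' Find illegal BIO transitions
#'
#' @param tags character tag vector.
#' @param schema a `tag_schema`.
#' @return integer vector of 1-based positions where a tag illegally
#'   continues the previous one (`I-` after `O`, after a different element,
#'   or at sequence start).
#' @export
validate_tags <- function(tags, schema) {
  tag_index(schema, tags)
  n <- length(tags)
  if (n == 0L) return(integer(0))
  bad <- integer(0)
  prev_el <- NA_character_; prev_kind <- "O"
  for (i in seq_len(n)) {
    t <- tags[i]
    kind <- if (t == "O") "O" else substr(t, 1L, 1L)
    e <- if (t == "O") NA_character_ else schema$element_of[[t]]
    if (kind == "I" && (prev_kind == "O" || is.na(prev_el) || prev_el != e)) {
      bad <- c(bad, i)
    }
    prev_el <- e; prev_kind <- kind
  }
  bad
}

#' Labeled segment and document constructors
#'
#' A `labeled_segment` is the unit of training and prediction: at most
#' `max_len` characters with an optional parallel BIO tag sequence and the
#' 0-based offset of its first character in the parent document. A
#' `picos_document` bundles the full text with its segments; segment texts
#' concatenate back to the document text exactly.
#'
#' @param chars character vector of single characters.
#' @param tags parallel tag vector or `NULL` for unlabeled segments.
#' @param offset 0-based offset of the segment in the document.
#' @param schema optional `tag_schema` used to validate the tags.
#' @return An object of class `labeled_segment`.
#' @export
labeled_segment <- function(chars, tags = NULL, offset = 0L, schema = NULL) {
  stopifnot(is.character(chars))
  if (!is.null(tags)) {
    if (length(tags) != length(chars)) {
      stop("tags length (", length(tags), ") != chars length (", length(chars), ")")
    }
    if (!is.null(schema)) {
      tag_index(schema, tags)
      bad <- validate_tags(tags, schema)
      if (length(bad)) stop("illegal BIO transition at position(s) ",
                            paste(bad, collapse = ", "))
    }
  }
  structure(list(chars = chars, tags = tags, offset = as.integer(offset)),
            class = "labeled_segment")
}

#' @rdname labeled_segment
#' @param doc_id document identifier, conventionally
#'   `NUMBER_YEAR_AUTHOR_TITLE`.
#' @param text full document text.
#' @param spans optional gold `entity_spans()` in document coordinates; when
#'   supplied (with `schema`) segments are cut around them and tagged.
#' @param max_len maximum segment length.
#' @export
picos_document <- function(doc_id, text, spans = NULL, schema = NULL,
                           max_len = 128L) {
  seg_texts <- segment_document(text, max_len = max_len, spans = spans)
  offsets <- c(0L, cumsum(nchar(seg_texts)))
  segments <- lapply(seq_along(seg_texts), function(i) {
    ch <- chars_of(seg_texts[i])
    tags <- NULL
    if (!is.null(spans) && !is.null(schema)) {
      lo <- offsets[i]; hi <- offsets[i + 1L]
      keep <- spans$start >= lo & spans$end <= hi
      local <- spans[keep, , drop = FALSE]
      local$start <- local$start - lo
      local$end <- local$end - lo
      tags <- spans_to_tags(local, length(ch), schema)
    }
    labeled_segment(ch, tags, offset = offsets[i])
  })
  structure(list(doc_id = doc_id, text = text, segments = segments,
                 spans = spans),
            class = "picos_document")
}

#' @export
print.picos_document <- function(x, ...) {
  cat("<picos_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      length(x$segments), " segment(s)",
      if (!is.null(x$spans)) paste0(", ", nrow(x$spans), " gold span(s)"),
      "\n", sep = "")
  invisible(x)
}

escape_bio_char <- function(ch) {
  ch <- gsub("\\", "\\\\", ch, fixed = TRUE)
  ch <- gsub("\t", "\\t", ch, fixed = TRUE)
  ch <- gsub("\n", "\\n", ch, fixed = TRUE)
  gsub("\r", "\\r", ch, fixed = TRUE)
}

unescape_bio_char <- function(ch) {
  ch <- gsub("\\r", "\r", ch, fixed = TRUE)
  ch <- gsub("\\n", "\n", ch, fixed = TRUE)
  ch <- gsub("\\t", "\t", ch, fixed = TRUE)
  gsub("\\\\", "\\", ch, fixed = TRUE)
}

#' Read and write BIO corpora
#'
#' The corpus dialect is CoNLL-style two-column UTF-8 text: one character,
#' a TAB, and its tag per line; a blank line after every segment; a
#' `###DOC <doc_id>` separator line before each document. Unlabeled
#' documents use one-column lines (no TAB). Tab, newline and backslash
#' characters are escaped as `\\t`, `\\n`, `\\\\` in the character column.
#' `write_bio_corpus()` emits the canonical form, so read and write are
#' mutually inverse on valid corpora.
#'
#' @param path file path.
#' @param schema optional `tag_schema`; when supplied every tag is checked
#'   against it.
#' @return `read_bio_corpus()`: list of `picos_document`;
#'   `write_bio_corpus()`: `path`, invisibly.
#' @export
read_bio_corpus <- function(path, schema = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_id <- NULL
  cur_segs <- list()
  seg_chars <- character(0); seg_tags <- character(0); seg_labeled <- NA
  flush_segment <- function() {
    if (length(seg_chars)) {
      cur_segs[[length(cur_segs) + 1L]] <<-
        list(chars = seg_chars,
             tags = if (isTRUE(seg_labeled)) seg_tags else NULL)
    }
    seg_chars <<- character(0); seg_tags <<- character(0); seg_labeled <<- NA
  }
  flush_doc <- function() {
    flush_segment()
    if (!is.null(cur_id)) {
      text <- paste(vapply(cur_segs, function(s) paste(s$chars, collapse = ""),
                           character(1)), collapse = "")
      offsets <- c(0L, cumsum(vapply(cur_segs, function(s) length(s$chars),
                                     integer(1))))
      segments <- lapply(seq_along(cur_segs), function(i) {
        labeled_segment(cur_segs[[i]]$chars, cur_segs[[i]]$tags,
                        offset = offsets[i])
      })
      spans <- NULL
      if (length(segments) && !is.null(schema) &&
          all(vapply(segments, function(s) !is.null(s$tags), logical(1)))) {
        sp <- lapply(segments, function(s) {
          suppressWarnings(tags_to_spans(s$tags, schema, text = text,
                                         offset = s$offset))
        })
        spans <- do.call(rbind, sp)
      }
      doc <- structure(list(doc_id = cur_id, text = text, segments = segments,
                            spans = spans),
                       class = "picos_document")
      docs[[length(docs) + 1L]] <<- doc
    }
    cur_id <<- NULL; cur_segs <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "###DOC ")) {
      flush_doc()
      cur_id <- sub("^###DOC ", "", line)
      if (!nzchar(cur_id)) stop("line ", ln, ": empty doc_id")
      next
    }
    if (line == "") { flush_segment(); next }
    if (is.null(cur_id)) stop("line ", ln, ": content before any ###DOC header")
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 1L) {
      if (isTRUE(seg_labeled)) stop("line ", ln, ": unlabeled line in labeled segment")
      seg_labeled <- FALSE
      seg_chars <- c(seg_chars, unescape_bio_char(fields[1L]))
    } else if (length(fields) == 2L) {
      if (isFALSE(seg_labeled)) stop("line ", ln, ": labeled line in unlabeled segment")
      seg_labeled <- TRUE
      if (!is.null(schema) && !(fields[2L] %in% schema$tags)) {
        stop("line ", ln, ": unknown tag '", fields[2L], "'")
      }
      seg_chars <- c(seg_chars, unescape_bio_char(fields[1L]))
      seg_tags <- c(seg_tags, fields[2L])
    } else {
      stop("line ", ln, ": expected 1 or 2 tab-separated fields, got ",
           length(fields))
    }
  }
  flush_doc()
  docs
}

#' @rdname read_bio_corpus
#' @param docs list of `picos_document`.
#' @export
write_bio_corpus <- function(docs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  for (doc in docs) {
    out <- c(out, paste0("###DOC ", doc$doc_id))
    for (seg in doc$segments) {
      ch <- escape_bio_char(seg$chars)
      lines <- if (is.null(seg$tags)) ch else paste0(ch, "\t", seg$tags)
      out <- c(out, lines, "")
    }
  }
  writeLines(enc2utf8(out), con, useBytes = TRUE, sep = "\n")
  invisible(path)
}
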