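#' Fit a character-level BiLSTM-CRF sequence labeler
#'
#' Trains the coarse evidence-span labeler: trainable character embeddings
#' feed a bidirectional LSTM encoder whose states project to per-tag
#' emission scores, decoded through a linear-chain CRF. The corpus is split
#' into train/held-out segments at `split_ratio` with a seeded shuffle;
#' optimization is AdamW on the mean per-segment negative log-likelihood.
#' Training is deterministic given `seed`.
#'
#' Alternatively, `encoder` may be a function mapping a character vector to
#' a fixed-dimension numeric matrix (one row per character) — an adapter for
#' externally computed representations such as pretrained-transformer
#' vectors. In that mode only the emission projection and CRF transitions
#' are trained.
#'
#' @param corpus list of `labeled_segment` (or of `picos_document`, whose
#'   segments are pooled); every segment must carry tags.
#' @param schema the `tag_schema` the tags are drawn from.
#' @param embed_dim,hidden_dim embedding and (per-direction) LSTM sizes.
#' @param epochs,batch_size,learning_rate,weight_decay AdamW schedule.
#' @param split_ratio train fraction in (0,1); default 0.9 (a 9:1 split).
#' @param seed integer seed controlling init, split and batch order.
#' @param bio_constraints forbid illegal BIO transitions in scoring and
#'   decoding (masked as `-Inf`).
#' @param encoder `"bilstm"` (default) or an encoding function (see above).
#' @param max_len segment length limit used when predicting raw documents.
#' @param verbose print per-epoch progress.
#' @return An object of class `crf_labeler` with components `params`,
#'   `vocab`, `schema`, `config`, and `history` (per-epoch `train_nll` and
#'   held-out strict entity `heldout_f1`).
#' @seealso [predict.crf_labeler()], [write_labeler()]
#' @export
crf_labeler <- function(corpus, schema,
                        embed_dim = 32L, hidden_dim = 48L,
                        epochs = 10L, batch_size = 8L,
                        learning_rate = 0.005, weight_decay = 0.01,
                        split_ratio = 0.9, seed = 1L,
                        bio_constraints = TRUE, encoder = "bilstm",
                        max_len = 128L, verbose = FALSE) {
  stopifnot(inherits(schema, "tag_schema"),
            split_ratio > 0, split_ratio < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  segs <- flatten_segments(corpus)
  if (length(segs) == 0L) stop("empty corpus")
  if (any(vapply(segs, function(s) is.null(s$tags), logical(1)))) {
    stop("all segments must be labeled for training")
  }
  n <- length(segs)
  n_train <- floor(n * split_ratio)
  if (n_train < 1L || n_train >= n) {
    stop("corpus too small to split at ratio ", split_ratio,
         " (", n, " segment(s)); need both partitions non-empty")
  }
  external <- is.function(encoder)
  config <- list(embed_dim = embed_dim, hidden_dim = hidden_dim,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 optimizer = "AdamW", split_ratio = split_ratio, seed = seed,
                 bio_constraints = bio_constraints,
                 encoder = if (external) "external" else "bilstm",
                 max_len = max_len)

  set.seed(seed)
  perm <- sample.int(n)
  train_idx <- perm[seq_len(n_train)]
  heldout_idx <- perm[(n_train + 1L):n]

  K <- length(schema$tags)
  allowed_m <- allowed_mask(schema, bio_constraints)
  tags_i <- lapply(segs, function(s) tag_index(schema, s$tags))

  vocab <- sort(unique(unlist(lapply(segs[train_idx], `[[`, "chars"))))
  xs <- lapply(segs, function(s) chars_to_ids(s$chars, vocab))

  gold_held <- lapply(heldout_idx, function(i) {
    suppressWarnings(tags_to_spans(segs[[i]]$tags, schema))
  })

  history <- data.frame(epoch = integer(0), train_nll = numeric(0),
                        heldout_f1 = numeric(0))
  if (!external) {
    params <- bc_init_params(length(vocab), K, embed_dim, hidden_dim)
    opt <- NULL
    for (ep in seq_len(epochs)) {
      order <- sample(train_idx)
      res <- bc_epoch(params, opt, xs, tags_i, allowed_m, order,
                      learning_rate, weight_decay, batch_size)
      params <- res$params
      opt <- res$opt
      f1 <- heldout_entity_f1(params, NULL, xs[heldout_idx], gold_held,
                              schema, allowed_m)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_nll = res$mean_nll,
                                           heldout_f1 = f1))
      if (verbose) message(sprintf("epoch %d: train NLL %.4f, held-out F1 %.4f",
                                   ep, res$mean_nll, f1))
    }
    model <- list(params = params, vocab = vocab, schema = schema,
                  config = config, history = history, encode_fun = NULL)
  } else {
    enc <- lapply(segs, function(s) encoder(s$chars))
    D <- ncol(enc[[1L]])
    params <- list(Wp = matrix(runif(K * D, -1 / sqrt(D), 1 / sqrt(D)), K, D),
                   bp = numeric(K),
                   T = matrix(0, K + 2L, K + 2L))
    state <- adamw_state(params)
    for (ep in seq_len(epochs)) {
      order <- sample(train_idx)
      nll_sum <- 0
      for (batch in split(order, ceiling(seq_along(order) / batch_size))) {
        g <- list(Wp = params$Wp * 0, bp = params$bp * 0, T = params$T * 0)
        for (i in batch) {
          E <- enc[[i]] %*% t(params$Wp) +
            matrix(params$bp, nrow(enc[[i]]), K, byrow = TRUE)
          gr <- crf_grad_cpp(E, params$T, allowed_m, tags_i[[i]])
          nll_sum <- nll_sum + gr$nll
          g$Wp <- g$Wp + t(gr$d_emissions) %*% enc[[i]]
          g$bp <- g$bp + colSums(gr$d_emissions)
          g$T <- g$T + gr$d_transitions
        }
        state <- adamw_step(params, state, lapply(g, `/`, length(batch)),
                            learning_rate,
                            wd = c(Wp = weight_decay, bp = 0, T = 0))
        params <- state$params
      }
      f1 <- heldout_entity_f1(params, enc, xs[heldout_idx], gold_held,
                              schema, allowed_m, heldout_idx = heldout_idx)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_nll = nll_sum / length(order),
                                           heldout_f1 = f1))
      if (verbose) message(sprintf("epoch %d: train NLL %.4f, held-out F1 %.4f",
                                   ep, nll_sum / length(order), f1))
    }
    model <- list(params = params, vocab = vocab, schema = schema,
                  config = config, history = history, encode_fun = encoder)
  }
  class(model) <- "crf_labeler"
  model
}

flatten_segments <- function(corpus) {
  if (inherits(corpus, "picos_document")) corpus <- list(corpus)
  segs <- list()
  for (x in corpus) {
    if (inherits(x, "picos_document")) segs <- c(segs, x$segments)
    else if (inherits(x, "labeled_segment")) segs <- c(segs, list(x))
    else stop("corpus entries must be picos_document or labeled_segment")
  }
  segs
}

chars_to_ids <- function(chars, vocab) {
  i <- match(chars, vocab)
  i[is.na(i)] <- length(vocab) + 1L # UNK
  as.integer(i)
}

allowed_mask <- function(schema, constrain) {
  m <- is.finite(crf_transitions(schema, constrain = constrain))
  storage.mode(m) <- "integer"
  m
}

decode_ids <- function(model, ids, chars = NULL) {
  allowed_m <- allowed_mask(model$schema, model$config$bio_constraints)
  if (is.null(model$encode_fun)) {
    bc_decode(model$params, ids, allowed_m)
  } else {
    E <- model$encode_fun(chars) %*% t(model$params$Wp)
    E <- E + matrix(model$params$bp, nrow(E), ncol(E), byrow = TRUE)
    Tm <- model$params$T
    Tm[allowed_m == 0L] <- -Inf
    viterbi_decode(E, Tm)$tags
  }
}

heldout_entity_f1 <- function(params, enc, xs_held, gold_held, schema,
                              allowed_m, heldout_idx = NULL) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(xs_held)) {
    pred_i <- if (is.null(enc)) {
      bc_decode(params, xs_held[[i]], allowed_m)
    } else {
      E <- enc[[heldout_idx[i]]] %*% t(params$Wp)
      E <- E + matrix(params$bp, nrow(E), ncol(E), byrow = TRUE)
      Tm <- params$T
      Tm[allowed_m == 0L] <- -Inf
      viterbi_decode(E, Tm)$tags
    }
    pred <- suppressWarnings(tags_to_spans(schema$tags[pred_i], schema))
    cc <- match_spans(gold_held[[i]], pred, match_config("strict"))
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  compute_prf(confusion_counts(tp, fp, fn))$f1
}

adamw_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(params = params, m = zeros, v = zeros, step = 0L)
}

adamw_step <- function(params, state, grads, lr, wd) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$step <- state$step + 1L
  t <- state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mh <- state$m[[nm]] / (1 - b1^t)
    vh <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] -
      lr * (mh / (sqrt(vh) + eps) + wd[[nm]] * params[[nm]])
  }
  state$params <- params
  state
}

#' Predict evidence spans in documents
#'
#' Segments each document (hard cuts at the model's `max_len`), decodes each
#' segment independently with constrained Viterbi, and maps the resulting
#' BIO spans back to document coordinates via segment offsets. Characters
#' absent from the training vocabulary map to the UNK embedding.
#'
#' @param object a fitted `crf_labeler`.
#' @param newdata a `picos_document`, a list of them, or a character vector
#'   of raw texts.
#' @param ... unused.
#' @return A named list (by doc_id) of `entity_spans()` tables.
#' @export
predict.crf_labeler <- function(object, newdata, ...) {
  docs <- as_document_list(newdata)
  out <- lapply(docs, function(doc) {
    seg_texts <- segment_document(doc$text, max_len = object$config$max_len)
    offsets <- c(0L, cumsum(nchar(seg_texts)))
    spans <- lapply(seq_along(seg_texts), function(i) {
      ch <- chars_of(seg_texts[i])
      if (length(ch) == 0L) return(entity_spans())
      ids <- chars_to_ids(ch, object$vocab)
      path <- decode_ids(object, ids, chars = ch)
      suppressWarnings(
        tags_to_spans(object$schema$tags[path], object$schema,
                      text = doc$text, offset = offsets[i])
      )
    })
    do.call(rbind, c(list(entity_spans()), spans))
  })
  names(out) <- vapply(docs, `[[`, character(1), "doc_id")
  out
}

as_document_list <- function(newdata) {
  if (inherits(newdata, "picos_document")) return(list(newdata))
  if (is.character(newdata)) {
    ids <- if (!is.null(names(newdata))) names(newdata)
           else sprintf("doc%03d", seq_along(newdata))
    return(lapply(seq_along(newdata), function(i) {
      picos_document(ids[i], newdata[i])
    }))
  }
  if (is.list(newdata)) return(newdata)
  stop("newdata must be documents or character texts")
}

#' @export
print.crf_labeler <- function(x, ...) {
  cat("<crf_labeler> ", x$config$encoder, " encoder, ",
      length(x$schema$tags), " tags, vocab ", length(x$vocab), "\n", sep = "")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epoch(s); final train NLL %.4f, held-out strict F1 %.4f\n",
                last$epoch, last$train_nll, last$heldout_f1))
  }
  invisible(x)
}

#' @export
summary.crf_labeler <- function(object, ...) {
  print(object)
  cat("  config: embed", object$config$embed_dim,
      "hidden", object$config$hidden_dim,
      "lr", object$config$learning_rate,
      "batch", object$config$batch_size,
      "split", object$config$split_ratio,
      "seed", object$config$seed, "\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.crf_labeler <- function(object, ...) {
  Tm <- object$params$T
  K <- length(object$schema$tags)
  dimnames(Tm) <- list(c(object$schema$tags, "START", "STOP"),
                       c(object$schema$tags, "START", "STOP"))
  Tm
}

#' @export
plot.crf_labeler <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_nll, type = "b", xlab = "epoch",
       ylab = "mean train NLL", main = "training loss", ...)
  plot(h$epoch, h$heldout_f1, type = "b", xlab = "epoch", ylim = c(0, 1),
       ylab = "held-out strict F1", main = "held-out entity F1", ...)
  invisible(h)
}

#' Save or load a labeler checkpoint
#'
#' The checkpoint is a single-file versioned container (R serialization)
#' holding parameters, vocabulary, tag schema and the config snapshot;
#' reloading reproduces predictions bit-identically. Models with a function
#' encoder store the function environment too and are only portable if that
#' function is self-contained.
#'
#' @param model a `crf_labeler`.
#' @param path file path.
#' @return `write_labeler()`: `path` invisibly; `read_labeler()`: the model.
#' @export
write_labeler <- function(model, path) {
  stopifnot(inherits(model, "crf_labeler"))
  saveRDS(list(format = "picosminer_labeler", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname write_labeler
#' @export
read_labeler <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "picosminer_labeler")) {
    stop("not a labeler checkpoint: ", path)
  }
  obj$model
}

#' Write a JSON-lines training log
#'
#' One JSON object per epoch: `{"epoch": ..., "train_nll": ...,
#' "heldout_f1": ...}`.
#'
#' @param model a fitted `crf_labeler`.
#' @param path output path.
#' @export
write_training_log <- function(model, path) {
  lines <- vapply(seq_len(nrow(model$history)), function(i) {
    jsonlite::toJSON(as.list(model$history[i, ]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
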