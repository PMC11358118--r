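# Linear-chain CRF reference implementation.
#
# Conventions shared with the C++ training engine:
#   * emissions: L x K matrix (L positions, K tags), finite entries;
#   * transitions: (K+2) x (K+2) matrix, rows = from, cols = to, with two
#     virtual states START = K+1 and STOP = K+2; -Inf marks a forbidden
#     transition (BIO constraint mask or structural START/STOP bans);
#   * a path t_1..t_L scores
#       T[START,t1] + sum_i E[i,ti] + sum_i T[ti,t(i+1)] + T[tL,STOP].
# These functions are the module's oracle surface: plain log-space dynamic
# programming, checked in the tests against exhaustive enumeration.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf (or any +Inf/NaN propagates)
  m + log(sum(exp(x - m)))
}

check_crf_shapes <- function(emissions, transitions) {
  if (!is.matrix(emissions) || !is.matrix(transitions)) {
    stop("emissions and transitions must be matrices")
  }
  K <- ncol(emissions)
  if (nrow(emissions) < 1L) stop("need at least one position (L >= 1)")
  if (nrow(transitions) != K + 2L || ncol(transitions) != K + 2L) {
    stop("transitions must be (K+2) x (K+2) with K = ", K,
         "; got ", nrow(transitions), " x ", ncol(transitions))
  }
  K
}

#' Linear-chain CRF: log partition function
#'
#' Computes `log sum_paths exp(score(path))` over all `K^L` tag paths with
#' the forward algorithm in log space (max-shifted log-sum-exp).
#'
#' @param emissions L x K score matrix.
#' @param transitions (K+2) x (K+2) score matrix with virtual states
#'   `START = K+1`, `STOP = K+2`; `-Inf` entries are forbidden transitions.
#' @return log partition function (scalar).
#' @export
crf_log_partition <- function(emissions, transitions) {
  K <- check_crf_shapes(emissions, transitions)
  L <- nrow(emissions)
  START <- K + 1L; STOP <- K + 2L
  alpha <- transitions[START, 1:K] + emissions[1L, ]
  if (L > 1L) {
    for (t in 2:L) {
      alpha <- vapply(1:K, function(k) {
        logsumexp(alpha + transitions[1:K, k]) + emissions[t, k]
      }, numeric(1))
    }
  }
  logsumexp(alpha + transitions[1:K, STOP])
}

#' Linear-chain CRF: score of one tag path
#'
#' @inheritParams crf_log_partition
#' @param tags integer vector of tag indices in `1..K`, length `L`.
#' @return path score (scalar).
#' @export
crf_sequence_score <- function(emissions, transitions, tags) {
  K <- check_crf_shapes(emissions, transitions)
  L <- nrow(emissions)
  tags <- as.integer(tags)
  if (length(tags) != L) stop("tags length ", length(tags), " != L = ", L)
  if (any(tags < 1L | tags > K)) stop("tag index out of range 1..", K)
  START <- K + 1L; STOP <- K + 2L
  s <- transitions[START, tags[1L]] + transitions[tags[L], STOP] +
    sum(emissions[cbind(1:L, tags)])
  if (L > 1L) s <- s + sum(transitions[cbind(tags[-L], tags[-1L])])
  s
}

#' Linear-chain CRF: negative log-likelihood of a tag path
#'
#' `crf_log_partition(...) - crf_sequence_score(...)`; non-negative up to
#' floating-point tolerance since the partition sum dominates any single
#' path.
#'
#' @inheritParams crf_sequence_score
#' @return scalar NLL.
#' @export
crf_nll <- function(emissions, transitions, tags) {
  crf_log_partition(emissions, transitions) -
    crf_sequence_score(emissions, transitions, tags)
}

#' Linear-chain CRF: Viterbi decoding
#'
#' Returns a maximum-scoring tag path. Ties are broken toward the lowest tag
#' index at every backtracking step, so all-equal scores yield the
#' lexicographically smallest path.
#'
#' @inheritParams crf_log_partition
#' @return list with `tags` (integer path, 1-based indices) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  K <- check_crf_shapes(emissions, transitions)
  L <- nrow(emissions)
  START <- K + 1L; STOP <- K + 2L
  delta <- transitions[START, 1:K] + emissions[1L, ]
  back <- matrix(0L, nrow = L, ncol = K)
  if (L > 1L) {
    for (t in 2:L) {
      new_delta <- numeric(K)
      for (k in 1:K) {
        cand <- delta + transitions[1:K, k]
        j <- which.max(cand) # first maximum = lowest index
        back[t, k] <- j
        new_delta[k] <- cand[j] + emissions[t, k]
      }
      delta <- new_delta
    }
  }
  final <- delta + transitions[1:K, STOP]
  path <- integer(L)
  path[L] <- which.max(final)
  if (L > 1L) {
    for (t in L:2) path[t - 1L] <- back[t, path[t]]
  }
  list(tags = path, score = final[path[L]])
}

#' BIO-constrained transition template
#'
#' Builds a `(K+2) x (K+2)` transition matrix of zeros with `-Inf` on the
#' transitions a BIO schema forbids: into `I-e` from anything other than
#' `B-e`/`I-e` (including from START), into START, and out of STOP.
#'
#' @param schema a `tag_schema`.
#' @param constrain if `FALSE`, only the structural START/STOP bans are set.
#' @return transition matrix usable with the `crf_*` functions.
#' @export
crf_transitions <- function(schema, constrain = TRUE) {
  K <- length(schema$tags)
  START <- K + 1L; STOP <- K + 2L
  T <- matrix(0, K + 2L, K + 2L)
  T[, START] <- -Inf        # nothing enters START
  T[STOP, ] <- -Inf         # nothing leaves STOP
  T[START, STOP] <- -Inf    # empty path impossible (L >= 1)
  if (constrain) {
    kinds <- ifelse(schema$tags == "O", "O", substr(schema$tags, 1L, 1L))
    els <- schema$element_of
    for (k in which(kinds == "I")) {
      ok_from <- which(kinds != "O" & els == els[[k]])
      T[setdiff(1:K, ok_from), k] <- -Inf
      T[START, k] <- -Inf
    }
  }
  T
}
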