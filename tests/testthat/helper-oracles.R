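# Independent oracles and shared fixtures.

# Exhaustive enumeration over all K^L tag paths: log partition, maximum
# path score and (first-in-lexicographic-order) argmax. Independent of the
# package's dynamic-programming implementations.
enum_crf <- function(E, Tm) {
  L <- nrow(E)
  K <- ncol(E)
  START <- K + 1L
  STOP <- K + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))[, L:1, drop = FALSE]
  # expand.grid varies the first column fastest; reversing columns makes the
  # row order lexicographic in the path, so which.max picks the smallest
  # maximizing path.
  paths <- paths[do.call(order, as.data.frame(paths)), , drop = FALSE]
  scores <- apply(paths, 1, function(p) {
    s <- Tm[START, p[1]] + Tm[p[L], STOP] + sum(E[cbind(seq_len(L), p)])
    if (L > 1L) s <- s + sum(Tm[cbind(p[-L], p[-1L])])
    s
  })
  mx <- max(scores)
  logZ <- if (is.finite(mx)) mx + log(sum(exp(scores - mx))) else mx
  list(logZ = logZ, max = mx, argmax = as.integer(paths[which.max(scores), ]))
}

random_crf_instance <- function(L, K, masked = FALSE) {
  E <- matrix(runif(L * K, -3, 3), L, K)
  Tm <- matrix(runif((K + 2)^2, -2, 2), K + 2, K + 2)
  Tm[, K + 1] <- -Inf
  Tm[K + 2, ] <- -Inf
  if (masked) {
    sub <- matrix(runif(K * K) < 0.2, K, K)
    Tm[1:K, 1:K][sub] <- -Inf
  }
  list(E = E, Tm = Tm)
}

# Random non-overlapping span set over a text of length n.
random_span_set <- function(n, registry, max_spans = 4L) {
  k <- sample(0:max_spans, 1L)
  spans <- entity_spans()
  occupied <- rep(FALSE, n)
  for (i in seq_len(k)) {
    len <- sample(1:4, 1L)
    if (n < len) next
    start <- sample(0:(n - len), 1L)
    idx <- (start + 1L):(start + len)
    if (any(occupied[idx])) next
    occupied[idx] <- TRUE
    el <- sample(registry$id, 1L)
    spans <- rbind(spans, entity_spans(el, start, start + len))
  }
  spans[order(spans$start), , drop = FALSE]
}

starter_ruleset <- function(registry = element_registry()) {
  compile_ruleset(system.file("extdata", "starter_rules.json",
                              package = "picosminer"),
                  registry = registry)
}

# Small CJK character pool for fuzzed texts.
chars_frag <- function() {
  strsplit(paste0("患者治疗组对照入例年龄岁医院诊断标准随机盲法",
                  "脱落失访不良反应数据统计分析结果"), "")[[1]]
}
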