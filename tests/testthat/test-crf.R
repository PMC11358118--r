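test_that("log partition matches closed forms on degenerate lattices", {
  # L=1, K=2, zero emissions and transitions: Z = 2
  E <- matrix(0, 1, 2)
  Tm <- matrix(0, 4, 4)
  expect_equal(crf_log_partition(E, Tm), log(2), tolerance = 1e-12)
  # all transitions masked except the path 1 -> 2
  E2 <- matrix(c(1, 0.5, 0, 2), 2, 2) # emissions
  Tm2 <- matrix(-Inf, 4, 4)
  Tm2[3, 1] <- 0.3 # START -> 1
  Tm2[1, 2] <- 0.7 # 1 -> 2
  Tm2[2, 4] <- -0.1 # 2 -> STOP
  want <- 0.3 + E2[1, 1] + 0.7 + E2[2, 2] - 0.1
  expect_equal(crf_log_partition(E2, Tm2), want, tolerance = 1e-12)
  expect_equal(viterbi_decode(E2, Tm2)$tags, c(1L, 2L))
})

test_that("sequence score accumulates start, emission, transition, stop terms", {
  E <- matrix(2.5, 1, 3)
  Tm <- matrix(0, 5, 5)
  Tm[4, 2] <- 0.4 # START -> 2
  Tm[2, 5] <- -0.2 # 2 -> STOP
  expect_equal(crf_sequence_score(E, Tm, 2L), 2.5 + 0.4 - 0.2)
  # zero transitions: sum of selected emissions
  set.seed(5)
  E2 <- matrix(rnorm(12), 4, 3)
  tags <- c(1L, 3L, 2L, 2L)
  expect_equal(crf_sequence_score(E2, matrix(0, 5, 5), tags),
               sum(E2[cbind(1:4, tags)]))
  # random instance vs independent term-by-term accumulation
  inst <- random_crf_instance(5, 4)
  tags5 <- sample(1:4, 5, replace = TRUE)
  hand <- inst$Tm[5, tags5[1]] + inst$Tm[tags5[5], 6]
  for (t in 1:5) hand <- hand + inst$E[t, tags5[t]]
  for (t in 1:4) hand <- hand + inst$Tm[tags5[t], tags5[t + 1]]
  expect_equal(crf_sequence_score(inst$E, inst$Tm, tags5), hand,
               tolerance = 1e-12)
  expect_error(crf_sequence_score(inst$E, inst$Tm, c(1L, 1L, 1L, 1L, 9L)),
               "out of range")
})

test_that("forward algorithm and Viterbi agree with exhaustive enumeration", {
  set.seed(42)
  for (i in 1:40) {
    L <- sample(1:5, 1)
    K <- sample(2:5, 1)
    inst <- random_crf_instance(L, K, masked = i %% 3 == 0)
    ref <- enum_crf(inst$E, inst$Tm)
    expect_equal(crf_log_partition(inst$E, inst$Tm), ref$logZ,
                 tolerance = 1e-8)
    vit <- viterbi_decode(inst$E, inst$Tm)
    expect_equal(vit$score, ref$max, tolerance = 1e-8)
    expect_equal(crf_sequence_score(inst$E, inst$Tm, vit$tags), vit$score,
                 tolerance = 1e-8)
  }
})

test_that("NLL is non-negative and matches the enumerated path distribution", {
  set.seed(9)
  for (i in 1:20) {
    inst <- random_crf_instance(3, 3)
    tags <- sample(1:3, 3, replace = TRUE)
    nll <- crf_nll(inst$E, inst$Tm, tags)
    expect_gte(nll, -1e-9)
    ref <- enum_crf(inst$E, inst$Tm)
    logp <- crf_sequence_score(inst$E, inst$Tm, tags) - ref$logZ
    expect_equal(nll, -logp, tolerance = 1e-8)
  }
  # single-path lattice: gold = that path -> NLL 0
  Tm <- matrix(-Inf, 4, 4)
  Tm[3, 1] <- 0; Tm[1, 2] <- 0; Tm[2, 4] <- 0
  E <- matrix(rnorm(4), 2, 2)
  expect_equal(crf_nll(E, Tm, c(1L, 2L)), 0, tolerance = 1e-9)
})

test_that("Viterbi breaks ties toward the lowest tag index", {
  E <- matrix(0, 3, 3)
  Tm <- matrix(0, 5, 5)
  expect_equal(viterbi_decode(E, Tm)$tags, c(1L, 1L, 1L))
})

test_that("shape mismatches are rejected", {
  expect_error(crf_log_partition(matrix(0, 2, 3), matrix(0, 4, 4)), "K")
  expect_error(viterbi_decode(matrix(0, 2, 3), matrix(0, 4, 4)), "K")
})

test_that("C++ CRF gradient matches finite differences of the reference NLL", {
  set.seed(31)
  L <- 4; K <- 3
  inst <- random_crf_instance(L, K)
  inst$Tm[!is.finite(inst$Tm)] <- 0 # keep structural mask only via `allowed`
  allowed <- matrix(1L, K + 2, K + 2)
  allowed[, K + 1] <- 0L
  allowed[K + 2, ] <- 0L
  tags <- sample(1:K, L, replace = TRUE)
  eff <- function(Tm) { Tm[allowed == 0L] <- -Inf; Tm }
  gr <- picosminer:::crf_grad_cpp(inst$E, inst$Tm, allowed, tags)
  expect_equal(gr$nll, crf_nll(inst$E, eff(inst$Tm), tags), tolerance = 1e-6)
  h <- 1e-6
  for (probe in list(c(1, 2), c(3, 1), c(4, 3))) {
    Ep <- inst$E; Ep[probe[1], probe[2]] <- Ep[probe[1], probe[2]] + h
    Em <- inst$E; Em[probe[1], probe[2]] <- Em[probe[1], probe[2]] - h
    fd <- (crf_nll(Ep, eff(inst$Tm), tags) -
             crf_nll(Em, eff(inst$Tm), tags)) / (2 * h)
    expect_equal(gr$d_emissions[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
  for (probe in list(c(1, 2), c(K + 1, 1), c(2, K + 2))) {
    Tp <- inst$Tm; Tp[probe[1], probe[2]] <- Tp[probe[1], probe[2]] + h
    Tn <- inst$Tm; Tn[probe[1], probe[2]] <- Tn[probe[1], probe[2]] - h
    fd <- (crf_nll(inst$E, eff(Tp), tags) -
             crf_nll(inst$E, eff(Tn), tags)) / (2 * h)
    expect_equal(gr$d_transitions[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
})

test_that("constrained decoding never emits an illegal BIO transition", {
  reg <- element_registry()
  sch <- tag_schema(reg)
  K <- length(sch$tags)
  allowed <- matrix(1L, K + 2, K + 2)
  allowed[!is.finite(crf_transitions(sch, constrain = TRUE))] <- 0L
  set.seed(77)
  params <- picosminer:::bc_init_params(30L, K, 8L, 8L)
  params$T <- matrix(rnorm((K + 2)^2, sd = 2), K + 2, K + 2) # adversarial
  for (i in 1:20) {
    x <- sample.int(31L, sample(1:40, 1), replace = TRUE)
    path <- picosminer:::bc_decode(params, x, allowed)
    expect_equal(validate_tags(sch$tags[path], sch), integer(0))
  }
})

test_that("C++ emissions plus reference Viterbi reproduce the C++ decoder", {
  reg <- element_registry()
  sch <- tag_schema(reg)
  K <- length(sch$tags)
  Tm <- crf_transitions(sch, constrain = TRUE)
  allowed <- matrix(1L, K + 2, K + 2)
  allowed[!is.finite(Tm)] <- 0L
  set.seed(3)
  params <- picosminer:::bc_init_params(20L, K, 6L, 6L)
  x <- sample.int(21L, 15, replace = TRUE)
  E <- picosminer:::bc_emissions(params, x)
  eff <- params$T
  eff[allowed == 0L] <- -Inf
  expect_equal(viterbi_decode(E, eff)$tags,
               picosminer:::bc_decode(params, x, allowed))
})
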