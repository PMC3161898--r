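# Difference-vector decomposition, orderings, applicability, invariants.

test_that("candidate counts follow the boolean 2^s - 1 law and match the oracle", {
  toy <- toy_net()
  d1 <- toy$expected$d1
  cands <- candidate_reactions(d1)
  expect_length(cands, 7L)
  keys <- vapply(cands, paste, "", collapse = ",")
  expect_true(paste(toy$expected$r4, collapse = ",") %in% keys)
  expect_true(paste(toy$expected$r5, collapse = ",") %in% keys)
  # single nonzero entry: exactly one candidate
  expect_length(candidate_reactions(c(0L, 0L, -1L)), 1L)
  # oracle agreement incl. multi-token partial magnitudes
  for (d in list(c(-1L, -1L, 1L, 0L), c(-2L, 1L, 0L), c(2L, -1L, -1L, 1L))) {
    expect_setequal(vapply(candidate_reactions(d), paste, "", collapse = ","),
                    vapply(oracle_sign_vectors(d), paste, "", collapse = ","))
  }
})

test_that("invariants prune candidates exactly as a brute-force filter", {
  d1 <- toy_net()$expected$d1
  w <- c(0L, 1L, 1L, 0L, 0L, 0L)  # B + C conserved
  pruned <- candidate_reactions(d1, invariants = list(w))
  expect_length(pruned, 3L)
  manual <- Filter(function(r) sum(w * r) == 0, candidate_reactions(d1))
  expect_identical(decomposition_keys(list(pruned)), decomposition_keys(list(manual)))
})

test_that("decompositions enumerate every multiset summing to the difference", {
  toy <- toy_net()
  d1 <- toy$expected$d1
  cands <- candidate_reactions(d1)
  decs <- decompositions(d1, cands)
  expect_length(decs, 5L)  # set partitions of the 3-place support
  keys <- decomposition_keys(decs)
  expect_true(paste(sort(c(paste(toy$expected$r4, collapse = ","),
                           paste(toy$expected$r5, collapse = ","))), collapse = ";")
              %in% keys)
  expect_true(paste(d1, collapse = ",") %in% keys)  # singleton {d}
  expect_length(decompositions(c(0L, 2L), candidate_reactions(c(0L, 2L))), 2L)
  expect_length(decompositions(c(0L, -1L), candidate_reactions(c(0L, -1L))), 1L)
})

test_that("decompositions agree with the brute-force oracle on random differences", {
  set.seed(41)
  for (rep in 1:25) {
    P <- sample(2:6, 1)
    d <- integer(P)
    while (!any(d != 0L)) d <- sample(c(-1L, 0L, 1L), P, replace = TRUE)
    cands <- candidate_reactions(d)
    expect_identical(decomposition_keys(decompositions(d, cands)),
                     oracle_decompositions(d, cands))
  }
  # and one multi-token case
  d <- c(-2L, 1L, 1L)
  expect_identical(decomposition_keys(decompositions(d, candidate_reactions(d))),
                   oracle_decompositions(d, candidate_reactions(d)))
})

test_that("ordering counts are multinomial coefficients", {
  toy <- toy_net()
  pair <- list(toy$expected$r4, toy$expected$r5)
  expect_length(ordered_sequences(pair), 2L)
  expect_length(ordered_sequences(pair[1]), 1L)
  three <- list(c(1L, 0L), c(0L, 1L), c(-1L, 0L))
  expect_length(ordered_sequences(three), 6L)
  # multiset with duplicates: k!/prod(m_i!)
  dup <- list(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L), c(-1L, -1L))
  expect_length(ordered_sequences(dup), factorial(5) / (factorial(2) * factorial(2)))
  expect_error(ordered_sequences(three, max_permutations = 5),
               class = "petrirec_cap_error")
})

test_that("applicability is the in-bounds successor test", {
  expect_false(is_applicable(c(-1L, 0L), c(0L, 1L)))          # below zero
  expect_false(is_applicable(c(0L, 1L), c(0L, 1L), capacity = 1L))  # above capacity
  toy <- toy_net()
  expect_true(is_applicable(toy$expected$d1, toy$m0))
})

test_that("intermediate-state walks validate every prefix and keep order-dependent y states", {
  toy <- toy_net()
  r4 <- toy$expected$r4; r5 <- toy$expected$r5
  w1 <- walk_intermediates(toy$m0, list(r4, r5))
  w2 <- walk_intermediates(toy$m0, list(r5, r4))
  expect_true(w1$ok && w2$ok)
  expect_false(identical(w1$intermediates, w2$intermediates))
  expect_identical(w1$final, unname(toy$m0 + toy$expected$d1))
  expect_identical(w2$final, w1$final)
  bad <- walk_intermediates(c(0L, 0L), list(c(-1L, 0L), c(0L, 1L)))
  expect_false(bad$ok)
  expect_identical(bad$violating_step, 1L)
  expect_error(walk_intermediates(c(1L), list()), class = "petrirec_validation_error")
})

test_that("place-pair invariants are detected from the case-study data", {
  sm <- pho_state_matrix_cached()
  invs <- auto_pinvariants(sm)
  pair_names <- vapply(invs, function(w) paste(names(w)[w != 0], collapse = "+"), "")
  for (expected in c("Pst-P+Pst", "PhoU-I+PhoU-A", "PhoR+PhoR-P", "PhoB+PhoB-P"))
    expect_true(expected %in% pair_names)
  # a conserved triple is only found when nominated
  expect_false(any(vapply(invs, function(w) sum(w != 0) == 3L, TRUE)))
  with_triple <- auto_pinvariants(sm, nominate = list(c("pi-pp", "pi-cp", "po-pp")))
  expect_true(any(vapply(with_triple, function(w)
    identical(names(which(w != 0)), c("pi-pp", "pi-cp", "po-pp")), TRUE)))
  # user invariants are verified, not trusted
  good <- integer(16); names(good) <- sm$components
  good[c("PhoR", "PhoR-P")] <- 1L
  expect_length(auto_pinvariants(sm, invariants = list(good), pairs = FALSE), 1L)
  bad <- integer(16); names(bad) <- sm$components
  bad[c("pi-pp", "PhoB")] <- 1L
  expect_error(auto_pinvariants(sm, invariants = list(bad), pairs = FALSE),
               "violated at state", class = "petrirec_validation_error")
})

test_that("degenerate state matrices yield no invariants", {
  sm <- pho_state_matrix_cached()
  empty <- sm
  empty$states <- empty$states[, 0, drop = FALSE]
  empty$segment <- integer(0); empty$terminal <- logical(0)
  expect_length(auto_pinvariants(empty), 0L)
})

test_that("combinatorial guards are hard errors", {
  d <- rep(c(-1L, 1L), 8)
  expect_error(candidate_reactions(d, max_candidates = 100),
               class = "petrirec_cap_error")
  d1 <- toy_net()$expected$d1
  expect_error(decompositions(d1, candidate_reactions(d1), max_decompositions = 2),
               class = "petrirec_cap_error")
})
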