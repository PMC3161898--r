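# Catalog construction, net composition, enumeration and replay.

test_that("the toy catalog column contains the documented alternatives", {
  toy <- toy_net()
  cat_ <- toy_catalog_cached()
  col1 <- cat_$columns[[1]]
  expect_identical(unname(col1$difference), unname(toy$expected$d1))
  # the single-reaction alternative (the original wiring) is present
  singletons <- Filter(function(alt)
    length(alt$reactions) == 1L &&
      identical(unname(alt$reactions[[1]]$r), unname(toy$expected$d1)),
    col1$alternatives)
  expect_length(singletons, 1L)
  expect_identical(format(singletons[[1]]$reactions[[1]]$f), "1")
  # the r4-first split carries exactly the controls A and not-F
  r4_first <- Filter(function(alt)
    length(alt$reactions) == 2L &&
      identical(unname(alt$reactions[[1]]$r), unname(toy$expected$r4)) &&
      identical(unname(alt$reactions[[2]]$r), unname(toy$expected$r5)),
    col1$alternatives)
  expect_length(r4_first, 2L)
  expect_setequal(vapply(r4_first, function(alt) format(alt$reactions[[1]]$f), ""),
                  c("A", "\u00acF"))
})

test_that("composition merges identical transitions and verifies by replay", {
  cat_ <- toy_catalog_cached()
  rec <- compose_net(cat_, rep(1L, length(cat_$columns)))
  expect_true(rec$report$ok)
  expect_error(compose_net(cat_, c(9999L, 1L, 1L, 1L)),
               "out of range", class = "petrirec_validation_error")
})

test_that("enumeration counts, limits and order behave as documented", {
  cat_ <- toy_catalog_cached()
  sizes <- column_sizes(cat_)
  res0 <- enumerate_nets(cat_, limit = 0)
  expect_identical(res0$count, prod(sizes))
  expect_length(res0$nets, 0L)
  res5 <- enumerate_nets(cat_, limit = 5)
  # selections that coincide after merging are deduplicated and counted
  expect_identical(length(res5$nets) + res5$duplicates, 5L)
  # canonical order: first net is the all-ones selection
  expect_identical(res5$selections[[1]], rep(1L, length(sizes)))
  # soundness: every streamed net passes replay
  res <- enumerate_nets(cat_, limit = 40)
  expect_true(all(vapply(res$nets, function(n) n$report$ok, TRUE)))
})

test_that("pair invariants can make the catalog unique, giving a single net", {
  sm <- compile_state_matrix(unique_chain_experiments())
  cat_ <- build_catalog(sm)
  expect_identical(column_sizes(cat_), c(1L, 1L))
  res <- enumerate_nets(cat_, limit = 10)
  expect_identical(res$count, 1)
  expect_length(res$nets, 1L)
  expect_identical(res$duplicates, 0L)
  expect_true(res$nets[[1]]$report$ok)
})

test_that("a single-state matrix gives a zero-column catalog and an empty net", {
  flat <- matrix(1L, 3, 2, dimnames = list(NULL, c("A", "B")))
  sm <- compile_state_matrix(list(experiment(flat, id = "flat")))
  cat_ <- build_catalog(sm)
  expect_length(cat_$columns, 0L)
  res <- enumerate_nets(cat_, limit = 1)
  expect_identical(res$count, 1)
  expect_length(res$nets[[1]]$net$transitions, 0L)
  expect_true(res$nets[[1]]$report$ok)
})

test_that("an unsatisfiable difference vector is a diagnosed failure", {
  # x0 -> x1 -> x2 with x2 terminal and x2 == x0: every split of the
  # first difference is applied at a marking identical to an applicable
  # terminal state (group II), so its column is empty
  vals <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 0L))
  colnames(vals) <- c("A", "B")
  sm <- compile_state_matrix(list(experiment(vals, id = "loop")))
  expect_error(build_catalog(sm), "difference vector",
               class = "petrirec_infeasible_error")
})

test_that("replay verification reports terminal-deadness violations", {
  sm <- compile_state_matrix(unique_chain_experiments())
  cat_ <- build_catalog(sm)
  rec <- enumerate_nets(cat_, limit = 1)$nets[[1]]
  # a mislabelled always-on reaction enabled at the terminal state
  rec$net <- add_transition(rec$net, "rogue", consume = c(B = 1L), produce = c(A = 1L))
  rep2 <- verify_replay(rec, sm)
  expect_false(rep2$ok)
  expect_match(rep2$terminal_violations, "rogue")
})

test_that("the case-study catalog reproduces the published solution structure", {
  cat_ <- pho_catalog_cached()
  sizes <- column_sizes(cat_)
  expect_identical(length(sizes), 11L)
  # sampled selections all replay, including deadness at the 10 terminals
  set.seed(3)
  picks <- list(rep(1L, 11), sizes,
                vapply(sizes, function(s) sample.int(s, 1), 1L))
  for (sel in picks) {
    rec <- compose_net(cat_, sel)
    expect_true(rec$report$ok)
  }
})

test_that("strict merge mode accepts the case-study composition", {
  sm <- pho_state_matrix_cached()
  cat_ <- build_catalog(sm, run_config(merge = "strict"))
  rec <- compose_net(cat_, rep(1L, length(cat_$columns)))
  expect_true(rec$report$ok)
})
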