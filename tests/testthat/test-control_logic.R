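# Group classification, exact boolean minimisation, subnet translation.

toy_states <- function() {
  toy <- toy_net()
  sm <- compile_state_matrix(toy$experiments)
  list(toy = toy, sm = sm,
       x0 = sm$states[, 1, drop = FALSE],
       x4 = sm$states[, 5, drop = FALSE])
}

test_that("reactions are classified into groups I/II/III", {
  ts <- toy_states()
  r4 <- ts$toy$expected$r4
  # r4 is applicable at the terminal state -> group III
  expect_identical(classify_reaction(r4, ts$x0, ts$x4), "III")
  # a reaction inapplicable at the terminal -> group I
  rA <- c(-1L, 0L, 0L, 0L, 0L, 0L)
  expect_identical(classify_reaction(rA, ts$x0, ts$x4), "I")
  # applied at a marking identical to an applicable terminal -> group II
  expect_identical(classify_reaction(r4, ts$x4, ts$x4), "II")
})

test_that("the canonical single-witness case yields exactly the two controls", {
  ts <- toy_states()
  crs <- derive_controls(ts$toy$expected$r4, ts$x0, ts$x4, rownames(ts$x0))
  expect_length(crs, 2L)
  expect_setequal(vapply(crs, function(cr) format(cr$f), ""),
                  c("A", "\u00acF"))
  # group I: single constant-true control
  crs1 <- derive_controls(c(-1L, 0L, 0L, 0L, 0L, 0L), ts$x0, ts$x4, rownames(ts$x0))
  expect_length(crs1, 1L)
  expect_identical(format(crs1[[1]]$f), "1")
  # group II: deleted, with a reason
  crs2 <- derive_controls(ts$toy$expected$r4, ts$x4, ts$x4, rownames(ts$x0))
  expect_length(crs2, 0L)
  expect_match(attr(crs2, "reason"), "terminal")
})

test_that("minimisation returns all optima and handles edge cases", {
  ts <- toy_states()
  covers <- minimize_boolean(ts$x0, ts$x4)
  expect_setequal(cover_keys(covers), c("A", "!F"))
  expect_identical(format(minimize_boolean(ts$x0, ts$x4[, 0, drop = FALSE])[[1]]), "1")
  expect_error(minimize_boolean(ts$x0, ts$x0),
               class = "petrirec_no_function_error")
  expect_error(minimize_boolean(ts$x0, ts$x4, qm_variable_cap = 3L),
               class = "petrirec_cap_error")
})

test_that("a forced two-term cover is found and matches the oracle", {
  # two on-states with opposite values in every informative place force
  # one term per on-state
  places <- c("A", "B", "C", "D")
  on <- matrix(c(1L, 1L, 0L, 0L,
                 0L, 0L, 1L, 1L), nrow = 4, dimnames = list(places, NULL))
  off <- matrix(c(1L, 0L, 1L, 0L,
                  0L, 1L, 0L, 1L), nrow = 4, dimnames = list(places, NULL))
  covers <- minimize_boolean(on, off, places)
  expect_true(all(vapply(covers, function(f) length(f$terms), 1L) == 2L))
  expect_identical(cover_keys(covers), oracle_min_covers(on, off, places))
})

test_that("minimisation agrees with exhaustive DNF search on random 4-variable cases", {
  set.seed(7)
  places <- c("A", "B", "C", "D")
  done <- 0L
  while (done < 30L) {
    marks <- unique(t(matrix(sample(0:1, 4 * 7, replace = TRUE), nrow = 4)))
    if (nrow(marks) < 3L) next
    n_on <- sample(1:2, 1)
    on <- t(marks[seq_len(n_on), , drop = FALSE])
    off <- t(marks[(n_on + 1):min(nrow(marks), n_on + 3), , drop = FALSE])
    rownames(on) <- rownames(off) <- places
    expect_identical(cover_keys(minimize_boolean(on, off, places)),
                     oracle_min_covers(on, off, places))
    done <- done + 1L
  }
})

test_that("every derived control separates its on-set from its off-set", {
  cat_ <- pho_catalog_cached()
  for (col in cat_$columns) for (alt in col$alternatives) for (cr in alt$reactions) {
    for (j in seq_len(ncol(cr$on_states)))
      expect_true(control_eval(cr$f, cr$on_states[, j]))
    for (j in seq_len(ncol(cr$off_states)))
      expect_false(control_eval(cr$f, cr$off_states[, j]))
  }
})

test_that("an input place never acts as the sole distinguishing literal", {
  # under boolean capacities an input place of r holds a token wherever r
  # is applicable, so it cannot separate on-states from off-states
  cat_ <- pho_catalog_cached()
  for (col in cat_$columns) for (alt in col$alternatives) for (cr in alt$reactions) {
    for (term in cr$f$terms) {
      if (length(term) == 1L && term > 0L && length(cr$f$terms) == 1L &&
          ncol(cr$off_states) > 0L)
        expect_true(cr$r[names(term)] >= 0L)
    }
  }
})

test_that("subnets realise the reaction vector and its control term by term", {
  ts <- toy_states()
  crs <- derive_controls(ts$toy$expected$r4, ts$x0, ts$x4, rownames(ts$x0))
  byf <- stats::setNames(crs, vapply(crs, function(cr) format(cr$f), ""))
  netA <- to_subnet(byf[["A"]], base_id = "r4")
  aA <- netA$arcs
  expect_identical(aA$kind[aA$place == "A"], "read")
  expect_identical(aA$kind[aA$place == "B"], "input")
  expect_identical(aA$kind[aA$place == "C"], "output")
  netF <- to_subnet(byf[["\u00acF"]], base_id = "r4")
  expect_identical(netF$arcs$kind[netF$arcs$place == "F"], "inhibitory")
  # two-term control: two transitions sharing the standard arcs
  cr2 <- petrirec:::new_creaction(ts$toy$expected$r4,
                                  control_fn(c("A"), c("!F")),
                                  ts$x0, ts$x4, rownames(ts$x0))
  net2 <- to_subnet(cr2, base_id = "r4")
  expect_length(net2$transitions, 2L)
  expect_identical(unname(reaction_vector(net2, "r4.1")),
                   unname(reaction_vector(net2, "r4.2")))
})

test_that("subnet enabling equals applicability AND control value", {
  ts <- toy_states()
  crs <- derive_controls(ts$toy$expected$r4, ts$x0, ts$x4, rownames(ts$x0))
  set.seed(11)
  for (cr in crs) {
    net <- to_subnet(cr)
    for (rep in 1:40) {
      m <- stats::setNames(sample(0:1, 6, replace = TRUE), rownames(ts$x0))
      lhs <- length(enabled_transitions(net, m)) > 0L
      rhs <- is_applicable(cr$r, m) && control_eval(cr$f, m)
      expect_identical(lhs, rhs)
    }
  }
})

test_that("control functions print, evaluate and canonicalise consistently", {
  f <- control_fn(c("C", "!D"))
  expect_identical(format(f), "C \u2227 \u00acD")
  m <- c(A = 1L, C = 1L, D = 1L)
  expect_false(control_eval(f, m))
  m["D"] <- 0L
  expect_true(control_eval(f, m))
  g <- control_fn(c("!D", "C"), c("C", "!D"))  # duplicate terms collapse
  expect_identical(petrirec:::control_key(g), petrirec:::control_key(f))
  expect_true(control_eval(control_true(), m))
  expect_error(control_fn(c("A", "!A")), class = "petrirec_validation_error")
})
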