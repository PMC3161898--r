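# Token-game semantics of the extended Petri net core.

test_that("stoichiometric firing follows arc weights and dies when they are unmet", {
  w <- water_net()
  expect_true(is_enabled(w$net, "T", c(3, 1, 0)))
  expect_identical(unname(fire(w$net, "T", c(3, 1, 0))), c(1L, 0L, 2L))
  expect_false(is_enabled(w$net, "T", c(1, 0, 2)))
  expect_identical(unname(reaction_vector(w$net, "T")), c(-2L, -1L, 2L))

  sim <- simulate_net(w$net, c(3, 1, 0))
  expect_identical(unname(sim$trajectory),
                   matrix(c(3L, 1L, 0L, 1L, 0L, 2L), nrow = 2, byrow = TRUE))
  expect_true(sim$terminal)

  expect_error(fire(w$net, "T", c(1, 0, 2)), class = "petrirec_contract_error")
  expect_error(is_enabled(w$net, "nope", c(3, 1, 0)),
               class = "petrirec_validation_error")
})

test_that("read and inhibitory arcs gate enabling without moving tokens", {
  net <- epn_net(c("A", "B", "C", "D"))
  net <- add_transition(net, "t", consume = c(A = 1L), produce = c(B = 1L),
                        read = "C", inhibit = "D")
  expect_false(is_enabled(net, "t", c(1, 0, 1, 1)))  # inhibitor marked
  expect_true(is_enabled(net, "t", c(1, 0, 1, 0)))   # inhibitor empty
  expect_false(is_enabled(net, "t", c(1, 0, 0, 0)))  # read place empty
  m1 <- fire(net, "t", c(1, 0, 1, 0))
  expect_identical(unname(m1), c(0L, 1L, 1L, 0L))    # C untouched

  # catalysis: the enzyme place of an enzymatic conversion is unchanged
  enz <- epn_net(c("S", "E", "P"))
  enz <- add_transition(enz, "cat", consume = c(S = 1L), produce = c(P = 1L),
                        read = "E")
  expect_identical(unname(fire(enz, "cat", c(1, 1, 0))), c(0L, 1L, 1L))
  expect_identical(unname(reaction_vector(enz, "cat")), c(-1L, 0L, 1L))
})

test_that("enabling respects output capacities", {
  net <- epn_net(c("A", "B"), capacity = 1L)
  net <- add_transition(net, "t", consume = c(A = 1L), produce = c(B = 1L))
  expect_false(is_enabled(net, "t", c(1, 1)))  # B full
  expect_true(is_enabled(net, "t", c(1, 0)))
})

test_that("explicit sequences are replayed exactly and errors name the step", {
  toy <- toy_net()
  sim <- simulate_net(toy$net, toy$m0, sequence = toy$firing_sequence)
  expect_identical(nrow(sim$trajectory), 5L)
  expect_true(sim$terminal)
  expect_error(simulate_net(toy$net, toy$m0, sequence = c("t2")),
               "step 1", class = "petrirec_contract_error")
  # empty net: trajectory is the initial marking, flagged terminal
  sim0 <- simulate_net(epn_net("A"), 1L)
  expect_identical(nrow(sim0$trajectory), 1L)
  expect_true(sim0$terminal)
})

test_that("firing properties hold on random instances", {
  for (seed in 1:10) {
    fx <- random_instance(seed)
    net <- fx$net
    traj <- fx$experiments[[1]]$values
    # determinism: replaying the recorded firing sequence is bit-identical
    sim1 <- simulate_net(net, fx$m0, sequence = fx$fired)
    sim2 <- simulate_net(net, fx$m0, sequence = fx$fired)
    expect_identical(sim1, sim2)
    m <- fx$m0
    for (t in fx$fired) {
      r <- reaction_vector(net, t)
      m2 <- fire(net, t, m)
      # token conservation: exactly the nonzero reaction-vector entries change
      expect_identical(unname(m2 - m), unname(r))
      # read/inhibitory neutrality
      arcs <- net$arcs[net$arcs$transition == t & net$arcs$kind %in% c("read", "inhibitory"), ]
      if (nrow(arcs)) expect_identical(m2[arcs$place], m[arcs$place])
      # validity closure
      expect_true(all(m2 >= 0 & m2 <= net$capacity))
      m <- m2
    }
  }
})

test_that("incidence matrix columns are the reaction vectors", {
  toy <- toy_net()
  im <- incidence_matrix(toy$net)
  expect_identical(dim(im), c(6L, 4L))
  for (t in toy$net$transitions)
    expect_identical(im[, t], reaction_vector(toy$net, t))
})

test_that("net construction rejects malformed input", {
  expect_error(epn_net(c("A", "A")), class = "petrirec_validation_error")
  expect_error(epn_net("A", capacity = 0), class = "petrirec_validation_error")
  net <- epn_net(c("A", "B"))
  expect_error(add_transition(net, "t", consume = c(Z = 1L)),
               "unknown place", class = "petrirec_validation_error")
  net <- add_transition(net, "t", consume = c(A = 1L))
  expect_error(add_transition(net, "t", consume = c(B = 1L)),
               "duplicate", class = "petrirec_validation_error")
  expect_error(check_marking <- fire(net, "t", c(1, 0, 0)),
               class = "petrirec_validation_error")
})
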