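# Packaged example systems and a seeded random-instance generator.
#
# Each fixture returns a list with a name, an optional generating net, the
# experiments (raw series, so that compilation is exercised), and a small
# set of documented expected outputs used by the tests.

#' Water synthesis net
#'
#' The classic three-place stoichiometry example: 2 H + O -> 2 W through a
#' single transition with arc weights 2, 1, 2.  From the marking (3,1,0)
#' the transition fires once to (1,0,2) and is then dead, because one
#' token of H is missing for the stoichiometry.
#'
#' @return Fixture list with `net`, `m0`, `experiments`, `expected`.
#' @export
water_net <- function() {
  net <- epn_net(c("H", "O", "W"), capacity = c(3L, 1L, 2L))
  net <- add_transition(net, "T", consume = c(H = 2L, O = 1L), produce = c(W = 2L))
  m0 <- c(H = 3L, O = 1L, W = 0L)
  sim <- simulate_net(net, m0)
  list(name = "water", net = net, m0 = m0,
       experiments = list(experiment(sim$trajectory, id = "water",
                                     label = "synthesis of water",
                                     terminal = TRUE)),
       expected = list(reaction_vector = c(H = -2L, O = -1L, W = 2L),
                       final = c(H = 1L, O = 0L, W = 2L)))
}

#' Six-place toy system
#'
#' A small net over places A..F built to exhibit the canonical worked
#' example of the reconstruction: its first difference vector
#' d1 = (-1,-1,+1,0,0,0) decomposes into 7 candidate reaction vectors;
#' the split of d1 into r4 = (0,-1,+1,0,0,0) and r5 = (-1,0,0,0,0,0) has
#' two orderings with distinct intermediate states; and for r4 the
#' initial state (token in A, F empty) and the terminal state (A empty,
#' token in F) differ in exactly those two places, so control derivation
#' returns precisely the alternatives f = A and f = -F.
#'
#' The wiring is a synthetic stand-in constructed to satisfy those
#' documented properties; its trajectory runs
#' x0 = (1,1,0,0,0,0) -> ... -> x4 = (0,1,0,0,0,1), terminal.
#'
#' @return Fixture list with `net`, `m0`, `firing_sequence`,
#'   `experiments`, `expected`.
#' @export
toy_net <- function() {
  net <- epn_net(LETTERS[1:6], capacity = 1L)
  net <- add_transition(net, "t1", consume = c(A = 1L, B = 1L), produce = c(C = 1L))
  net <- add_transition(net, "t2", consume = c(C = 1L), produce = c(D = 1L))
  net <- add_transition(net, "t3", consume = c(D = 1L), produce = c(E = 1L))
  net <- add_transition(net, "t4", consume = c(E = 1L), produce = c(B = 1L, F = 1L))
  m0 <- stats::setNames(c(1L, 1L, 0L, 0L, 0L, 0L), LETTERS[1:6])
  seqn <- c("t1", "t2", "t3", "t4")
  sim <- simulate_net(net, m0, sequence = seqn)
  list(name = "toy6", net = net, m0 = m0, firing_sequence = seqn,
       experiments = list(experiment(rbind(sim$trajectory,
                                           sim$trajectory[nrow(sim$trajectory), ]),
                                     id = "toy", label = "toy time series")),
       expected = list(
         d1 = stats::setNames(c(-1L, -1L, 1L, 0L, 0L, 0L), LETTERS[1:6]),
         n_candidates = 7L, n_decompositions = 5L,
         r4 = stats::setNames(c(0L, -1L, 1L, 0L, 0L, 0L), LETTERS[1:6]),
         r5 = stats::setNames(c(-1L, 0L, 0L, 0L, 0L, 0L), LETTERS[1:6]),
         r4_controls = c("A", "\u00acF")))
}

pho_transitions <- function() {
  # generating model of the phosphate regulon case (transcribed wiring):
  # read arcs encode catalysis/conformational coupling, e.g. PhoR
  # autophosphorylation requires active PhoU and an intact PhoR
  # phosphorylation site.
  list(
    uptake       = list(consume = c("pi-pp" = 1L), produce = c("pi-cp" = 1L), read = "Pst-P"),
    pst_dephos   = list(consume = c("Pst-P" = 1L), produce = c("Pst" = 1L)),
    phoU_act     = list(consume = c("PhoU-I" = 1L), produce = c("PhoU-A" = 1L), read = "Pst"),
    phoR_phos    = list(consume = c("PhoR" = 1L), produce = c("PhoR-P" = 1L),
                        read = c("PhoU-A", "PhoR-S")),
    transfer     = list(consume = c("PhoR-P" = 1L, "PhoB" = 1L),
                        produce = c("PhoR" = 1L, "PhoB-P" = 1L), read = "PhoB-S"),
    phoA_syn     = list(produce = c("PhoA" = 1L), read = c("PhoB-P", "PhoA-T")),
    phoA_export  = list(consume = c("PhoA" = 1L), produce = c("PhoA-pp" = 1L)),
    po_degrade   = list(consume = c("po-pp" = 1L), produce = c("pi-pp" = 1L), read = "PhoA-pp"),
    pst_phos     = list(consume = c("Pst" = 1L), produce = c("Pst-P" = 1L), read = "pi-pp"),
    phoU_deact   = list(consume = c("PhoU-A" = 1L), produce = c("PhoU-I" = 1L), read = "Pst-P"),
    phoB_dephos  = list(consume = c("PhoB-P" = 1L), produce = c("PhoB" = 1L), read = "PhoU-I")
  )
}

#' Phosphate regulon case study
#'
#' The packaged test case: a 16-component model of the bacterial
#' phosphate-starvation (Pho) regulon, with places for periplasmic and
#' cytoplasmic inorganic phosphate (pi-pp, pi-cp), periplasmic organic
#' phosphate (po-pp), the phosphorylated/dephosphorylated forms of the
#' PstSCAB transporter, PhoU in its active/inactive conformation, the
#' two-component proteins PhoR and PhoB with their phosphorylation sites
#' (PhoR-S, PhoB-S), the alkaline-phosphatase gene (PhoA-T), its
#' cytoplasmic product (PhoA) and the periplasmic enzyme (PhoA-pp).
#'
#' Eleven experiments (wild-type under three nutrient conditions, four
#' gene deletions and two phosphorylation-site deletions, each encoded as
#' an initial-marking change) yield 46 compiled states with 10 flagged
#' terminal states and 11 distinct difference vectors.  The generating
#' net is transcribed from the published model figure (not from printed
#' tables); the state table itself is transcribed from printed tables and
#' checksummed in the tests.
#'
#' @return Fixture list with `net`, `experiments`, `state_matrix`,
#'   `printed_reactions` (the 19 printed difference/decomposed-reaction
#'   columns), `wildtype_sequence` and `expected`.
#' @export
pho_regulon <- function() {
  sm_path <- system.file("extdata", "pho_states.tsv", package = "petrirec",
                         mustWork = TRUE)
  sm <- read_state_matrix(sm_path)
  net <- epn_net(sm$components, capacity = 1L)
  for (nm in names(pho_transitions())) {
    tr <- pho_transitions()[[nm]]
    net <- add_transition(net, nm,
                          consume = tr$consume %||% integer(0),
                          produce = tr$produce %||% integer(0),
                          read = tr$read %||% character(0))
  }
  experiments <- lapply(unique(sm$origin$experiment), function(id) {
    idx <- which(sm$origin$experiment == id)
    vals <- t(sm$states[, idx, drop = FALSE])
    term <- sm$terminal[idx[length(idx)]]
    # terminal experiments repeat their final measurement so that
    # compilation re-detects the flag from the raw series alone
    if (term || nrow(vals) == 1L) vals <- rbind(vals, vals[nrow(vals), ])
    experiment(vals, id = id, terminal = if (term) NA else FALSE)
  })
  printed <- utils::read.table(
    system.file("extdata", "pho_printed_reactions.tsv", package = "petrirec",
                mustWork = TRUE),
    header = TRUE, sep = "\t", check.names = FALSE, row.names = 1L)
  list(name = "pho_regulon", net = net, experiments = experiments,
       state_matrix = sm,
       printed_reactions = as.matrix(printed),
       wildtype_sequence = c("uptake", "pst_dephos", "phoU_act", "phoR_phos",
                             "transfer", "phoA_syn", "phoA_export", "po_degrade",
                             "pst_phos", "phoU_deact", "phoB_dephos"),
       expected = list(n_states = 46L, n_experiments = 11L, n_terminal = 10L,
                       n_differences = 11L))
}

#' Seeded random extended-net instance
#'
#' Generates a reproducible random extended Petri net (boolean
#' capacities, distinct single-token reaction vectors, at most one
#' control arc per transition drawn outside the transition's own
#' support), picks a random initial marking, and simulates a random
#' token game until deadlock.  Used by the small-scale completeness
#' oracle; sizes are therefore bounded.
#'
#' @param seed Integer seed; the same seed yields the identical instance.
#' @param n_places Number of places (at most 6).
#' @param n_transitions Number of transitions (at most 4).
#' @param control_density Probability that a transition carries a control
#'   arc.
#' @return Fixture list with `net`, `m0`, `experiments` (one deadlocked
#'   trajectory), `fired` (transition ids in firing order).
#' @export
random_instance <- function(seed, n_places = 5L, n_transitions = 3L,
                            control_density = 0.3) {
  if (n_places > 6L || n_transitions > 4L)
    pr_validation_error("random instances are bounded to 6 places / 4 transitions (oracle scale)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  places <- LETTERS[seq_len(n_places)]
  for (attempt in 1:100) {
    net <- epn_net(places, capacity = 1L)
    keys <- character(0)
    ok <- TRUE
    for (k in seq_len(n_transitions)) {
      for (try2 in 1:50) {
        n_in <- sample(1:2, 1L); n_out <- sample(1:2, 1L)
        support <- sample(places, min(n_in + n_out, n_places))
        ins <- support[seq_len(min(n_in, length(support) - 1L))]
        outs <- setdiff(support, ins)
        r <- stats::setNames(integer(n_places), places)
        r[ins] <- -1L; r[outs] <- 1L
        if (vec_key(r) %in% keys) next
        keys <- c(keys, vec_key(r))
        ctl_read <- character(0); ctl_inh <- character(0)
        rest <- setdiff(places, support)
        if (length(rest) && stats::runif(1) < control_density) {
          pl <- sample(rest, 1L)
          if (stats::runif(1) < 0.5) ctl_read <- pl else ctl_inh <- pl
        }
        net <- add_transition(net, sprintf("t%d", k),
                              consume = stats::setNames(rep(1L, length(ins)), ins),
                              produce = stats::setNames(rep(1L, length(outs)), outs),
                              read = ctl_read, inhibit = ctl_inh)
        break
      }
      if (length(net$transitions) < k) { ok <- FALSE; break }
    }
    if (!ok) next
    m0 <- stats::setNames(sample(0:1, n_places, replace = TRUE), places)
    m <- m0; traj <- list(m0); fired <- character(0)
    for (step in 1:12) {
      en <- enabled_transitions(net, m)
      if (!length(en)) break
      t <- if (length(en) == 1L) en else sample(en, 1L)
      m <- fire(net, t, m)
      traj[[length(traj) + 1L]] <- m
      fired <- c(fired, t)
    }
    if (length(enabled_transitions(net, m)) == 0L && length(fired) >= 1L) {
      vals <- do.call(rbind, traj)
      colnames(vals) <- places
      return(list(name = sprintf("random-%d", seed), net = net, m0 = m0,
                  fired = fired,
                  experiments = list(experiment(rbind(vals, vals[nrow(vals), ]),
                                                id = "sim", label = "random token game"))))
    }
  }
  pr_validation_error(sprintf("no deadlocking instance found for seed %d", seed))
}
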