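# Catalog construction and net composition.
#
# The solution catalog is the implicit representation of every net
# consistent with the data: one column per distinct difference vector,
# each column holding the complete list of alternative controlled-reaction
# sequences able to generate that difference.  Explicit nets are composed
# by picking one alternative per column; the enumeration order is a mixed
# radix counter over the column indices, so the "first solution" is
# reproducible.

#' Default run configuration
#'
#' @param capacity Optional capacity override (named or positional).
#' @param invariants User-supplied invariant weight vectors.
#' @param nominate Place sets to test as additional unweighted invariants.
#' @param auto_invariants Scan place pairs for data-supported invariants.
#' @param max_candidates,max_decompositions,max_permutations Combinatorial
#'   guards per difference vector; exceeding one is a hard error.
#' @param qm_variable_cap Exact-minimisation variable cap.
#' @param limit Default enumeration limit.
#' @param merge Cross-column merge mode for identical reaction vectors:
#'   `"keep-distinct"` (default, per-column independence) or `"strict"`
#'   (pool on-states of identical (r, f) pairs and re-derive; composition
#'   is rejected when pooling breaks on/off separation).
#' @param seed Seed recorded in the provenance snapshot.
#' @param verbose Emit progress messages to stderr.
#' @return A `petrirec_config` list.
#' @export
run_config <- function(capacity = NULL, invariants = list(), nominate = list(),
                       auto_invariants = TRUE,
                       max_candidates = 10000, max_decompositions = 10000,
                       max_permutations = 10000, qm_variable_cap = 24L,
                       limit = 100L, merge = c("keep-distinct", "strict"),
                       seed = NULL, verbose = FALSE) {
  merge <- match.arg(merge)
  for (nm in c("max_candidates", "max_decompositions", "max_permutations"))
    as_count(get(nm), nm)
  structure(list(capacity = capacity, invariants = invariants,
                 nominate = nominate, auto_invariants = auto_invariants,
                 max_candidates = max_candidates,
                 max_decompositions = max_decompositions,
                 max_permutations = max_permutations,
                 qm_variable_cap = qm_variable_cap, limit = limit,
                 merge = merge, seed = seed, verbose = verbose),
            class = "petrirec_config")
}

#' Build the solution catalog
#'
#' Runs the full reconstruction pipeline on a compiled state matrix: for
#' each distinct difference vector, candidate reaction vectors (pruned by
#' place invariants) are enumerated, all decompositions and firing orders
#' are generated, intermediate states are validated against the capacity
#' bounds from every witness state, reactions are classified against the
#' flagged terminal states (group II sequences are deleted), and all
#' minimal control functions are derived.  Every surviving combination of
#' one minimum cover per reaction becomes one alternative
#' controlled-reaction sequence of the column.
#'
#' @param sm An `epn_state_matrix`.
#' @param config A [run_config()].
#' @return Object of class `epn_catalog`: `components`, `capacity`,
#'   `terminals`, `invariants`, `columns` (each with `difference`,
#'   `witnesses`, `sequences` (part lists with their full cover sets)
#'   and `alternatives` (the expanded controlled-reaction sequences),
#'   and `config`.
#' @export
build_catalog <- function(sm, config = run_config()) {
  stopifnot(inherits(sm, "epn_state_matrix"))
  if (!is.null(config$capacity))
    sm$capacity <- stats::setNames(
      rep_len(as.integer(config$capacity), length(sm$components)), sm$components)
  dm <- difference_matrix(sm)
  invariants <- auto_pinvariants(sm, nominate = config$nominate,
                                 invariants = config$invariants,
                                 pairs = isTRUE(config$auto_invariants))
  capacity <- sm$capacity
  terms_m <- terminal_states(sm)
  msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  columns <- vector("list", ncol(dm$entries))
  for (j in seq_len(ncol(dm$entries))) {
    d <- dm$entries[, j]
    wit <- dm$witnesses[[j]]
    msg("difference %d/%d: %s", j, ncol(dm$entries), fmt_vec(d, sm$components))
    cands <- candidate_reactions(d, invariants, config$max_candidates)
    decs <- decompositions(d, cands, config$max_decompositions)
    sequences <- list()
    for (dec in decs) {
      for (sq in ordered_sequences(dec, config$max_permutations)) {
        # pool application states over all witnesses; reject the ordering
        # if it is out of bounds from any witness start
        on_by_r <- list()
        ok <- TRUE
        for (w in wit) {
          start <- sm$states[, w + 1L]
          walk <- walk_intermediates(start, sq, capacity)
          if (!walk$ok) { ok <- FALSE; break }
          for (k in seq_along(sq)) {
            key <- vec_key(sq[[k]])
            on_by_r[[key]] <- cbind(on_by_r[[key]], walk$applied_at[k, ])
          }
        }
        if (!ok) next
        controls <- list()
        dead <- FALSE
        for (key in names(on_by_r)) {
          r <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
          on <- on_by_r[[key]]
          rownames(on) <- sm$components
          crs <- derive_controls(r, on, terms_m, sm$components, capacity,
                                 config$qm_variable_cap)
          if (!length(crs)) { dead <- TRUE; break }
          controls[[key]] <- crs
        }
        if (dead) next
        sequences[[length(sequences) + 1L]] <-
          list(parts = sq, controls = controls)
      }
    }
    if (!length(sequences))
      pr_infeasible_error(sprintf(
        "no controlled-reaction sequence can generate difference vector %d (%s)",
        j, fmt_vec(d, sm$components)))
    alternatives <- list()
    for (s in seq_along(sequences)) {
      sq <- sequences[[s]]
      part_keys <- vapply(sq$parts, vec_key, "")
      choice_sets <- lapply(unique(part_keys), function(k) seq_along(sq$controls[[k]]))
      names(choice_sets) <- unique(part_keys)
      grid <- expand.grid(rev(choice_sets), KEEP.OUT.ATTRS = FALSE)
      for (g in seq_len(nrow(grid))) {
        picks <- as.list(grid[g, , drop = FALSE])
        alternatives[[length(alternatives) + 1L]] <- list(
          sequence_id = s,
          reactions = lapply(seq_along(sq$parts), function(k) {
            key <- part_keys[k]
            sq$controls[[key]][[picks[[key]]]]
          })
        )
      }
    }
    columns[[j]] <- list(difference = d, witnesses = wit,
                         sequences = sequences, alternatives = alternatives)
  }
  structure(list(components = sm$components, capacity = capacity,
                 terminals = terms_m, invariants = invariants,
                 columns = columns, state_matrix = sm, config = config),
            class = "epn_catalog")
}

#' @export
print.epn_catalog <- function(x, ...) {
  sizes <- vapply(x$columns, function(col) length(col$alternatives), 1L)
  cat(sprintf("Solution catalog: %d difference vector(s); alternatives per column: %s\n",
              length(x$columns), paste(sizes, collapse = " ")))
  cat(sprintf("total nets: %s; ambiguous columns: %d\n",
              format(prod(sizes), big.mark = ","), sum(sizes > 1L)))
  invisible(x)
}

#' Numbers of alternatives per catalog column
#' @param cat An `epn_catalog`.
#' @return Integer vector.
#' @export
column_sizes <- function(cat) {
  vapply(cat$columns, function(col) length(col$alternatives), 1L)
}

compose_transition_rows <- function(cat, selection) {
  # returns a list of transition specs: list(r, term, label)
  specs <- list()
  for (j in seq_along(cat$columns)) {
    col <- cat$columns[[j]]
    alt <- col$alternatives[[selection[j]]]
    for (k in seq_along(alt$reactions)) {
      cr <- alt$reactions[[k]]
      terms <- if (length(cr$f$terms)) cr$f$terms else
        list(stats::setNames(integer(0), character(0)))
      for (tk in seq_along(terms)) {
        specs[[length(specs) + 1L]] <- list(
          r = cr$r, term = terms[[tk]], cr = cr,
          label = sprintf("d%d.%d%s", j, k,
                          if (length(terms) > 1L) sprintf(".%d", tk) else ""))
      }
    }
  }
  specs
}

#' Compose an explicit net from the catalog
#'
#' Combines the selected alternative of every column into one extended
#' Petri net.  Transitions with identical standard and control arcs that
#' are selected through several columns merge into a single transition.
#' In `merge = "strict"` mode, identical (r, f) pairs additionally pool
#' their on-states and the composition is rejected when the pooled on-set
#' intersects the off-set.
#'
#' @param cat An `epn_catalog`.
#' @param selection Integer vector, one alternative index per column
#'   (recycled, so `1` selects the first alternative everywhere).
#' @return Object of class `epn_reconstruction`: `net`, `selection`,
#'   `report` (from [verify_replay()]).
#' @export
compose_net <- function(cat, selection) {
  stopifnot(inherits(cat, "epn_catalog"))
  selection <- rep_len(as.integer(selection), length(cat$columns))
  for (j in seq_along(cat$columns)) {
    if (selection[j] < 1L || selection[j] > length(cat$columns[[j]]$alternatives))
      pr_validation_error(sprintf("selection %d out of range for column %d (size %d)",
                                  selection[j], j,
                                  length(cat$columns[[j]]$alternatives)))
  }
  specs <- compose_transition_rows(cat, selection)
  sig <- vapply(specs, function(sp) paste(vec_key(sp$r), term_key(sp$term), sep = "/"), "")
  merged <- !duplicated(sig)
  if (identical(cat$config$merge, "strict")) {
    rf_key <- vapply(specs, function(sp) paste(vec_key(sp$r), control_key(sp$cr$f)), "")
    for (key in unique(rf_key)) {
      grp <- specs[rf_key == key]
      on <- do.call(cbind, lapply(grp, function(sp) sp$cr$on_states))
      off <- do.call(cbind, lapply(grp, function(sp) sp$cr$off_states))
      if (length(intersect(apply(on, 2L, vec_key), apply(off, 2L, vec_key))))
        pr_infeasible_error(
          "strict merge: pooled on-states of an identical (r, f) pair intersect its off-states")
    }
  }
  net <- epn_net(cat$components, cat$capacity)
  for (sp in specs[merged]) {
    r <- sp$r
    net <- add_transition(net, sp$label,
                          consume = -r[r < 0L], produce = r[r > 0L],
                          read = names(sp$term)[sp$term > 0L],
                          inhibit = names(sp$term)[sp$term < 0L])
  }
  rec <- structure(list(net = net, selection = selection, catalog = cat),
                   class = "epn_reconstruction")
  # a catalog read back from JSON does not carry its state matrix; the
  # replay report is then NA rather than a claim either way
  rec$report <- if (!is.null(cat$state_matrix)) verify_replay(rec, cat$state_matrix)
    else list(ok = NA, step_violations = character(0),
              terminal_violations = character(0))
  rec
}

#' @export
print.epn_reconstruction <- function(x, ...) {
  cat(sprintf("Reconstructed net (selection %s): %s\n",
              paste(x$selection, collapse = ","),
              if (x$report$ok) "replay verified" else "REPLAY VIOLATIONS"))
  print(x$net)
  invisible(x)
}

#' Enumerate composed nets
#'
#' Walks the selections in canonical mixed-radix order (last column
#' fastest) and composes up to `limit` nets.  The total count is the
#' product of the column sizes; nets that coincide after transition
#' merging are deduplicated among the streamed nets and reported.
#'
#' @param cat An `epn_catalog`.
#' @param limit Maximum number of nets to materialise (`0` for count only).
#' @return List with `count` (total selections), `nets` (list of
#'   `epn_reconstruction`), `selections`, and `duplicates` (number of
#'   streamed nets discarded as duplicates after merging).
#' @export
enumerate_nets <- function(cat, limit = cat$config$limit) {
  sizes <- column_sizes(cat)
  count <- prod(sizes)
  limit <- min(as_count(limit, "limit"), count)
  nets <- list(); sels <- list(); seen <- character(0); dup <- 0L
  if (!length(sizes)) {
    if (limit > 0) {
      rec <- compose_net(cat, integer(0))
      nets <- list(rec); sels <- list(integer(0))
    }
    return(list(count = 1, nets = nets, selections = sels, duplicates = 0L))
  }
  sel <- rep(1L, length(sizes))
  taken <- 0L
  repeat {
    if (taken >= limit) break
    rec <- compose_net(cat, sel)
    key <- net_signature(rec$net)
    if (key %in% seen) {
      dup <- dup + 1L
    } else {
      seen <- c(seen, key)
      nets[[length(nets) + 1L]] <- rec
      sels[[length(sels) + 1L]] <- sel
    }
    taken <- taken + 1L
    # mixed-radix increment, last column fastest
    j <- length(sel)
    repeat {
      sel[j] <- sel[j] + 1L
      if (sel[j] <= sizes[j]) break
      sel[j] <- 1L
      j <- j - 1L
      if (j == 0L) break
    }
    if (j == 0L) break
  }
  list(count = count, nets = nets, selections = sels, duplicates = dup)
}

net_signature <- function(net) {
  a <- net$arcs
  by_t <- split(a, a$transition)
  keys <- sort(vapply(by_t, function(rows) {
    rows <- rows[order(rows$kind, rows$place), ]
    paste(rows$kind, rows$place, rows$weight, sep = ":", collapse = ";")
  }, ""))
  paste(keys, collapse = "|")
}

#' Verify a reconstruction by replay
#'
#' Checks that (a) for every consecutive state pair of the state matrix,
#' the selected controlled-reaction sequence of that pair's difference
#' vector fires legally on the composed net, passing exactly through its
#' intermediate states; and (b) at every flagged terminal state no
#' transition of the net is enabled (otherwise the state would not be
#' terminal).  Violations are report content, not errors.
#'
#' @param rec An `epn_reconstruction`.
#' @param sm The `epn_state_matrix` the catalog was built on.
#' @return List with `ok`, `step_violations` (character), and
#'   `terminal_violations` (character).
#' @export
verify_replay <- function(rec, sm) {
  net <- rec$net
  cat_ <- rec$catalog
  diff_key <- vapply(cat_$columns, function(col) vec_key(col$difference), "")
  step_bad <- character(0)
  n <- ncol(sm$states)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (sm$segment[i + 1L] != sm$segment[i]) next
    d <- sm$states[, i + 1L] - sm$states[, i]
    if (!any(d != 0L)) next
    j <- match(vec_key(d), diff_key)
    if (is.na(j)) {
      step_bad <- c(step_bad, sprintf("state %d: difference not in catalog", i - 1L))
      next
    }
    alt <- cat_$columns[[j]]$alternatives[[rec$selection[j]]]
    m <- sm$states[, i]
    ok <- TRUE
    for (cr in alt$reactions) {
      t <- find_firing(net, cr, m)
      if (is.na(t)) { ok <- FALSE; break }
      m <- m + cr$r
    }
    if (!ok || !all(m == sm$states[, i + 1L]))
      step_bad <- c(step_bad, sprintf(
        "state %d -> %d: selected sequence cannot be fired", i - 1L, i))
  }
  term_bad <- character(0)
  tm <- terminal_states(sm)
  for (j in seq_len(ncol(tm))) {
    en <- enabled_transitions(net, tm[, j])
    if (length(en))
      term_bad <- c(term_bad, sprintf(
        "terminal state %s enables transition(s) %s",
        colnames(tm)[j], paste(en, collapse = ", ")))
  }
  list(ok = !length(step_bad) && !length(term_bad),
       step_violations = step_bad, terminal_violations = term_bad)
}

# transition of `net` that realises controlled reaction `cr` and is
# enabled at marking m; NA if none.
find_firing <- function(net, cr, m) {
  for (t in net$transitions) {
    if (!identical(unname(reaction_vector(net, t)), unname(cr$r))) next
    if (is_enabled(net, t, m)) return(t)
  }
  NA_character_
}
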