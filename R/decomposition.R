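# Exhaustive decomposition of difference vectors into candidate reaction
# vectors, enumeration of decompositions and firing orders, intermediate
# states and the applicability test.
#
# Combinatorial guards are hard errors (condition class
# 'petrirec_cap_error'), never silent truncation: the number of candidate
# vectors grows as prod(|d_i|+1)-1 and decompositions/permutations can
# explode on dense difference vectors.

#' Candidate reaction vectors of a difference vector
#'
#' All nonzero vectors whose entries are sign-compatible with and bounded
#' by the difference ("equal to or partially contributing"); for boolean
#' data each entry is 0 or the difference entry, so a difference with `s`
#' nonzero entries yields `2^s - 1` candidates.  Candidates violating a
#' place invariant (`weights . r != 0`) are removed.  Output is in
#' canonical lexicographic order.
#'
#' @param d Integer difference vector.
#' @param invariants List of non-negative integer weight vectors over the
#'   same component ordering.
#' @param max_candidates Guard on the candidate count.
#' @return List of integer vectors.
#' @export
candidate_reactions <- function(d, invariants = list(), max_candidates = Inf) {
  d <- as.integer(d)
  if (!any(d != 0L)) pr_validation_error("difference vector is zero")
  ranges <- lapply(d, function(di) {
    if (di == 0L) 0L else if (di > 0L) 0L:di else di:0L
  })
  n_total <- prod(vapply(ranges, length, 1L)) - 1
  if (n_total > max_candidates)
    pr_cap_error(sprintf("candidate set size (%d) exceeds max_candidates (%s)",
                         n_total, format(max_candidates)))
  grid <- as.matrix(rev(expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)))
  dimnames(grid) <- NULL
  keep <- rowSums(grid != 0L) > 0L
  for (w in invariants) {
    w <- as.numeric(w)
    if (length(w) != length(d))
      pr_validation_error("invariant weight vector has wrong length")
    keep <- keep & (as.vector(grid %*% w) == 0)
  }
  grid <- grid[keep, , drop = FALSE]
  grid <- grid[lex_order_rows(grid), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

#' All decompositions of a difference vector
#'
#' Every multiset of candidate reaction vectors summing exactly to the
#' difference (including the singleton `{d}` whenever no invariant removed
#' it).  Deterministic order: parts within a decomposition and the list of
#' decompositions are canonically (lexicographically) sorted.
#'
#' @param d Integer difference vector.
#' @param candidates Candidate list from [candidate_reactions()].
#' @param max_decompositions Guard on the number of decompositions.
#' @return List of decompositions; each is a list of integer vectors.
#' @export
decompositions <- function(d, candidates, max_decompositions = Inf) {
  d <- as.integer(d)
  res <- list()
  k <- length(candidates)
  feasible <- function(r, rem) {
    all(r == 0L | (sign(r) == sign(rem) & abs(r) <= abs(rem)))
  }
  rec <- function(idx, rem, acc) {
    if (!any(rem != 0L)) {
      if (length(acc)) {
        if (length(res) + 1L > max_decompositions)
          pr_cap_error(sprintf("decomposition count exceeds max_decompositions (%s)",
                               format(max_decompositions)))
        res[[length(res) + 1L]] <<- acc
      }
      return(invisible())
    }
    if (idx > k) return(invisible())
    for (j in idx:k) {
      r <- candidates[[j]]
      if (feasible(r, rem)) rec(j, rem - r, c(acc, list(r)))
    }
  }
  rec(1L, d, list())
  res
}

#' All orderings of a decomposition's parts
#'
#' Distinct permutations of the multiset of reaction vectors; the count is
#' the multinomial coefficient of the part multiplicities.
#'
#' @param parts List of integer reaction vectors.
#' @param max_permutations Guard on the ordering count.
#' @return List of orderings, each a list of integer vectors.
#' @export
ordered_sequences <- function(parts, max_permutations = Inf) {
  if (!length(parts)) return(list())
  keys <- vapply(parts, vec_key, "")
  perms <- multiset_permutations(keys, max_permutations)
  lapply(perms, function(p) parts[p])
}

#' Applicability of a reaction vector to a state
#'
#' A reaction is applicable to a state if adding it yields a valid
#' successor state, i.e. no place drops below zero or exceeds its capacity.
#'
#' @param r Integer reaction vector.
#' @param x Integer marking.
#' @param capacity Integer capacities (recycled).
#' @return `TRUE` or `FALSE`.
#' @export
is_applicable <- function(r, x, capacity = 1L) {
  capacity <- rep_len(as.integer(capacity), length(x))
  y <- as.integer(x) + as.integer(r)
  all(y >= 0L & y <= capacity)
}

#' Walk the intermediate states of an ordered reaction sequence
#'
#' Starting from `start`, the parts are added one by one; every prefix sum
#' must be a valid marking.  On success the intermediate states (the `y`
#' states strictly between start and end) and the final state are
#' returned; otherwise the violating step is reported.
#'
#' @param start Integer marking.
#' @param parts Ordered list of reaction vectors.
#' @param capacity Integer capacities.
#' @return List with `ok`; if `ok`, `applied_at` (matrix: the state at
#'   which each part is applied, one row per part), `intermediates`
#'   (matrix of the strictly intermediate states, 0 or more rows) and
#'   `final`; else `violating_step`.
#' @export
walk_intermediates <- function(start, parts, capacity = 1L) {
  if (!length(parts)) pr_validation_error("empty reaction sequence")
  capacity <- rep_len(as.integer(capacity), length(start))
  x <- as.integer(start)
  applied_at <- matrix(0L, nrow = length(parts), ncol = length(start))
  for (k in seq_along(parts)) {
    if (!is_applicable(parts[[k]], x, capacity))
      return(list(ok = FALSE, violating_step = k))
    applied_at[k, ] <- x
    x <- x + as.integer(parts[[k]])
  }
  inter <- if (length(parts) > 1L) applied_at[-1L, , drop = FALSE] else
    matrix(integer(0), nrow = 0L, ncol = length(start))
  list(ok = TRUE, applied_at = applied_at, intermediates = inter, final = x)
}

#' Detect place invariants supported by the data
#'
#' Scans all place pairs for an unweighted token sum that is constant
#' within every experiment segment of the state matrix (the value may
#' differ between experiments, e.g. when a mutant lacks the protein whose
#' forms the invariant couples).  User-nominated place sets and explicit
#' weight vectors are verified the same way and pass through; a violated
#' user invariant is a validation error naming the offending state.
#'
#' @param sm An `epn_state_matrix`.
#' @param nominate List of character vectors of place names to test as
#'   additional unweighted invariants.
#' @param invariants List of user-supplied weight vectors to verify.
#' @param pairs Scan all place pairs (set `FALSE` to check only nominated
#'   and user-supplied invariants).
#' @return List of invariant weight vectors (named integer vectors over the
#'   components).
#' @export
auto_pinvariants <- function(sm, nominate = list(), invariants = list(),
                             pairs = TRUE) {
  stopifnot(inherits(sm, "epn_state_matrix"))
  P <- length(sm$components)
  out <- list()
  conserved <- function(w) {
    sums <- as.vector(w %*% sm$states)
    bad <- which(stats::ave(sums, sm$segment, FUN = function(v) v - v[1L]) != 0)
    if (!length(bad)) NULL else bad[1L] - 1L
  }
  if (isTRUE(pairs) && ncol(sm$states) && P >= 2L) {
    for (p in seq_len(P - 1L)) for (q in seq(p + 1L, P)) {
      w <- integer(P); w[c(p, q)] <- 1L
      if (is.null(conserved(w))) {
        names(w) <- sm$components
        out[[length(out) + 1L]] <- w
      }
    }
  }
  for (set in nominate) {
    unknown <- setdiff(set, sm$components)
    if (length(unknown))
      pr_validation_error(sprintf("nominated invariant names unknown place(s): %s",
                                  paste(unknown, collapse = ", ")))
    w <- as.integer(sm$components %in% set)
    names(w) <- sm$components
    if (is.null(conserved(w))) out[[length(out) + 1L]] <- w
  }
  for (w in invariants) {
    w <- rep_len(as.integer(w), P)
    names(w) <- sm$components
    bad <- conserved(w)
    if (!is.null(bad))
      pr_validation_error(sprintf(
        "user invariant (%s) violated at state %d", fmt_vec(w, sm$components), bad))
    out[[length(out) + 1L]] <- w
  }
  out
}
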