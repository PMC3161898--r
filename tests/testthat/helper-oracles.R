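# Independent brute-force oracles used by the property tests.  These are
# deliberately written with different algorithms than the package code
# they check.

# All nonzero sign-compatible vectors bounded by d, by per-position
# recursion (the package uses an expand.grid enumeration instead).
oracle_sign_vectors <- function(d) {
  res <- list()
  rec <- function(i, acc) {
    if (i > length(d)) {
      if (any(acc != 0L)) res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    vals <- if (d[i] == 0L) 0L else if (d[i] > 0L) 0L:d[i] else d[i]:0L
    for (v in vals) rec(i + 1L, c(acc, v))
  }
  rec(1L, integer(0))
  res
}

# All multisets of `vecs` summing to d, by enumerating index multisets
# with an L1-norm budget: sign-compatible parts add their L1 norms
# without cancellation, so a multiset summing to d has total L1 exactly
# |d|_1.  (Pruning on the norm only; the sum is checked at the end.)
oracle_decompositions <- function(d, vecs) {
  budget <- sum(abs(d))
  norms <- vapply(vecs, function(v) sum(abs(v)), 1)
  res <- character(0)
  n <- length(vecs)
  rec <- function(start, left, idx) {
    if (left == 0L) {
      s <- Reduce(`+`, vecs[idx])
      if (all(s == d)) {
        key <- paste(sort(vapply(vecs[idx], paste, "", collapse = ",")), collapse = ";")
        res <<- c(res, key)
      }
      return(invisible())
    }
    if (start > n) return(invisible())
    for (j in start:n)
      if (norms[j] <= left) rec(j, left - norms[j], c(idx, j))
  }
  rec(1L, budget, integer(0))
  sort(unique(res))
}

decomposition_keys <- function(decs) {
  sort(vapply(decs, function(parts)
    paste(sort(vapply(parts, paste, "", collapse = ",")), collapse = ";"), ""))
}

# Exhaustive minimum-DNF search over at most 4 boolean variables: all
# consistent terms are enumerated and covers of growing size are tried.
oracle_min_covers <- function(on, off, places) {
  P <- nrow(on)
  stopifnot(P <= 4L)
  lit_opts <- rep(list(c(0L, 1L, -1L)), P)   # absent / positive / negative
  grid <- as.matrix(expand.grid(lit_opts))
  terms <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid[i, ]
    idx <- which(v != 0L)
    if (!length(idx)) return(NULL)
    stats::setNames(v[idx], places[idx])
  })
  terms <- Filter(Negate(is.null), terms)
  sat <- function(term, x) {
    v <- x[match(names(term), places)]
    all((term > 0L & v >= 1L) | (term < 0L & v == 0L))
  }
  term_ok <- vapply(terms, function(tm)
    !any(vapply(seq_len(ncol(off)), function(j) sat(tm, off[, j]), TRUE)), TRUE)
  terms <- terms[term_ok]
  if (!length(terms)) return(NULL)
  cov <- lapply(terms, function(tm)
    which(vapply(seq_len(ncol(on)), function(j) sat(tm, on[, j]), TRUE)))
  need <- seq_len(ncol(on))
  for (k in seq_along(terms)) {
    found <- Filter(function(cb) all(need %in% unlist(cov[cb])),
                    utils::combn(seq_along(terms), k, simplify = FALSE))
    if (length(found)) {
      lits <- vapply(found, function(cb) sum(lengths(terms[cb])), 1)
      found <- found[lits == min(lits)]
      keys <- unique(vapply(found, function(cb) {
        tk <- vapply(terms[cb], function(tm) {
          tm <- tm[order(names(tm))]
          paste(ifelse(tm < 0L, paste0("!", names(tm)), names(tm)), collapse = "&")
        }, "")
        # same canonical term order as the package: size first, then key
        tk <- tk[order(lengths(terms[cb]), tk)]
        paste(tk, collapse = "|")
      }, ""))
      return(sort(keys))
    }
  }
  NULL
}

cover_keys <- function(covers) {
  sort(vapply(covers, petrirec:::control_key, ""))
}

# Replay a state matrix on a net: each consecutive within-segment pair
# must be realised by exactly one enabled transition, and flagged
# terminal states must be dead.
oracle_replay <- function(net, sm) {
  n <- ncol(sm$states)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (sm$segment[i + 1L] != sm$segment[i]) next
    d <- sm$states[, i + 1L] - sm$states[, i]
    hit <- Filter(function(t)
      is_enabled(net, t, sm$states[, i]) &&
        identical(unname(reaction_vector(net, t)), unname(d)),
      net$transitions)
    if (length(hit) < 1L) return(sprintf("no transition realises step %d", i - 1L))
    }
  for (j in which(sm$terminal)) {
    en <- enabled_transitions(net, sm$states[, j])
    if (length(en)) return(sprintf("terminal state %d enables %s", j - 1L,
                                   paste(en, collapse = ",")))
  }
  TRUE
}
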