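# Derivation of control functions: classification of reactions against
# terminal states, exact two-level boolean minimisation, and translation of
# controlled reactions into net fragments with read/inhibitory arcs.
#
# A control function is a DNF over place-presence literals: a positive
# literal means "at least one token", a negative literal "no token".  Each
# DNF term maps one-to-one to a transition; the term's positive literals
# become read arcs and its negative literals inhibitory arcs.
#
# Minimisation works on the on-set (markings where the reaction is
# applied, so f must be 1) and the off-set (terminal markings where the
# reaction is applicable, so f must be 0); every other marking is a
# don't-care, which preserves Petri-net nondeterminism.  The implementation
# is the exact Quine-McCluskey scheme specialised to this encoding: prime
# implicants are the minimal hitting sets of the off-states' disagreeing
# places (maximally general conjunctions that still exclude every
# off-state), and all minimum covers are found by exhaustive selection
# (Petrick-style), minimising first the term count, then the total literal
# count.  ALL optima are returned: equally small covers are genuine
# alternative regulatory mechanisms.

new_control <- function(terms) {
  structure(list(terms = terms), class = "epn_control")
}

#' Constant-true control function
#' @return An `epn_control` with no terms, evaluating to 1 everywhere.
#' @export
control_true <- function() new_control(list())

#' Build a control function from literal strings
#'
#' @param ... Each argument is one conjunctive term, a character vector of
#'   literals; `"A"` requires at least one token in place A, `"!A"`
#'   requires place A to be empty.  Terms are combined by OR.
#' @return An `epn_control`.
#' @examples
#' control_fn(c("A"))            # f = A
#' control_fn(c("C", "!D"))      # f = C AND NOT D
#' control_fn("A", "!F")         # f = A OR NOT F
#' @export
control_fn <- function(...) {
  terms <- lapply(list(...), function(lits) {
    pol <- ifelse(startsWith(lits, "!"), -1L, 1L)
    nm <- sub("^!", "", lits)
    if (anyDuplicated(nm))
      pr_validation_error("a term must not contain a place twice")
    stats::setNames(pol, nm)
  })
  canonical_control(new_control(terms))
}

canonical_term <- function(term) term[order(names(term))]

term_key <- function(term) {
  term <- canonical_term(term)
  paste(ifelse(term < 0L, paste0("!", names(term)), names(term)), collapse = "&")
}

canonical_control <- function(f) {
  terms <- lapply(f$terms, canonical_term)
  keys <- vapply(terms, term_key, "")
  terms <- terms[!duplicated(keys)]
  ord <- order(vapply(terms, length, 1L), vapply(terms, term_key, ""))
  new_control(terms[ord])
}

control_key <- function(f) {
  f <- canonical_control(f)
  if (!length(f$terms)) return("TRUE")
  paste(vapply(f$terms, term_key, ""), collapse = "|")
}

#' Evaluate a control function on a marking
#'
#' @param f An `epn_control`.
#' @param m Named integer marking (names must include every place
#'   mentioned in `f`).
#' @return `TRUE` or `FALSE`.
#' @export
control_eval <- function(f, m) {
  if (!length(f$terms)) return(TRUE)
  if (is.null(names(m)))
    pr_validation_error("marking must be named to evaluate a control function")
  for (term in f$terms) {
    v <- m[names(term)]
    if (anyNA(v))
      pr_validation_error("control function mentions a place absent from the marking")
    if (all((term > 0L & v >= 1L) | (term < 0L & v == 0L))) return(TRUE)
  }
  FALSE
}

#' @export
format.epn_control <- function(x, ...) {
  if (!length(x$terms)) return("1")
  # infix form with the conventional logic symbols (AND, OR, NOT)
  one <- function(term) {
    lits <- ifelse(term < 0L, paste0("\u00ac", names(term)), names(term))
    paste(lits, collapse = " \u2227 ")
  }
  paste(vapply(x$terms, one, ""), collapse = " \u2228 ")
}

#' @export
print.epn_control <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Classify a reaction against the terminal states
#'
#' Group I: the reaction is applicable to no terminal state, so it may be
#' enabled at all times and, by minimality, carries no control arcs.
#' Group II: the reaction is applied at a marking identical to a terminal
#' state where it is applicable; the control function would have to be 1
#' and 0 at the same marking, so the reaction is deleted.  Group III: all
#' other cases, where control by read/inhibitory arcs is possible.
#'
#' @param r Integer reaction vector.
#' @param on_states Matrix of markings where the reaction is applied
#'   (states in columns, components in rows).
#' @param terminals Matrix of terminal markings (states in columns).
#' @param capacity Integer capacities.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_reaction <- function(r, on_states, terminals, capacity = 1L) {
  if (!ncol(on_states)) pr_validation_error("empty on-state set")
  applicable <- vapply(seq_len(ncol(terminals)), function(j)
    is_applicable(r, terminals[, j], capacity), TRUE)
  if (!any(applicable)) return("I")
  off <- terminals[, applicable, drop = FALSE]
  on_keys <- apply(on_states, 2L, vec_key)
  off_keys <- apply(off, 2L, vec_key)
  if (length(intersect(on_keys, off_keys))) return("II")
  "III"
}

#' All minimum DNF covers separating on-states from off-states
#'
#' Returns every DNF over place-presence literals that evaluates to 1 on
#' all `on` markings and 0 on all `off` markings, has the minimum possible
#' number of terms, and among those the minimum total literal count.  All
#' other markings are don't-cares.  An empty off-set yields the
#' constant-true function.  Overlapping on/off sets admit no function
#' (condition `petrirec_no_function_error`).
#'
#' @param on,off Integer matrices of markings, components in rows, one
#'   marking per column.
#' @param places Character vector of place names (row order).
#' @param qm_variable_cap Refuse (rather than approximate) beyond this
#'   many places.
#' @return List of `epn_control` objects in canonical order.
#' @export
minimize_boolean <- function(on, off, places = rownames(on), qm_variable_cap = 24L) {
  P <- nrow(on)
  if (is.null(places)) places <- paste0("p", seq_len(P))
  if (P > qm_variable_cap)
    pr_cap_error(sprintf("%d places exceed qm_variable_cap (%d); refusing approximate minimisation",
                         P, qm_variable_cap))
  if (!ncol(off)) return(list(control_true()))
  on_keys <- apply(on, 2L, vec_key)
  off_keys <- apply(off, 2L, vec_key)
  if (length(intersect(on_keys, off_keys)))
    pr_stop("on- and off-sets overlap: no control function exists",
            "petrirec_no_function_error")
  on <- on[, !duplicated(on_keys), drop = FALSE]
  off <- off[, !duplicated(off_keys), drop = FALSE]

  # Prime implicants that cover on-state x: literals are fixed by x
  # (positive where x has tokens, negative where empty); a conjunction
  # excludes off-state o iff it contains a literal disagreeing with o.
  # Minimal hitting sets over the disagreement sets are exactly the prime
  # implicants covering x.
  primes_for <- function(x) {
    disagree <- lapply(seq_len(ncol(off)), function(j) {
      o <- off[, j]
      which((x >= 1L & o == 0L) | (x == 0L & o >= 1L))
    })
    if (any(lengths(disagree) == 0L)) return(list())
    universe <- sort(unique(unlist(disagree)))
    nu <- length(universe)
    bit_of <- bitwShiftL(1L, seq_len(nu) - 1L)           # bit per universe element
    mask_of <- function(idx) {
      b <- 0L
      for (i in match(idx, universe)) b <- bitwOr(b, bit_of[i])
      b
    }
    masks <- vapply(disagree, mask_of, 1L)
    suffix <- integer(nu + 1L)                           # bits available from i on
    for (i in nu:1L) suffix[i] <- bitwOr(suffix[i + 1L], bit_of[i])
    hits <- list()
    rec <- function(i, chosen, rem) {
      if (!length(rem)) {
        hits[[length(hits) + 1L]] <<- chosen
        return(invisible())
      }
      if (i > nu || any(bitwAnd(rem, suffix[i]) == 0L)) return(invisible())
      rec(i + 1L, chosen, rem)
      rec(i + 1L, c(chosen, universe[i]), rem[bitwAnd(rem, bit_of[i]) == 0L])
    }
    rec(1L, integer(0), masks)
    hmasks <- vapply(hits, mask_of, 1L)
    keep <- vapply(seq_along(hmasks), function(a)
      !any(hmasks != hmasks[a] & bitwAnd(hmasks, hmasks[a]) == hmasks), TRUE)
    lapply(hits[keep], function(s)
      stats::setNames(ifelse(x[s] >= 1L, 1L, -1L), places[s]))
  }

  all_primes <- list(); prime_keys <- character(0)
  for (j in seq_len(ncol(on))) {
    for (term in primes_for(on[, j])) {
      key <- term_key(term)
      if (!key %in% prime_keys) {
        prime_keys <- c(prime_keys, key)
        all_primes[[length(all_primes) + 1L]] <- term
      }
    }
  }
  if (!length(all_primes))
    pr_stop("no conjunction separates some on-state from the off-set",
            "petrirec_no_function_error")

  covers_on <- function(term, x) {
    v <- x[match(names(term), places)]
    all((term > 0L & v >= 1L) | (term < 0L & v == 0L))
  }
  coverage <- lapply(all_primes, function(term)
    which(vapply(seq_len(ncol(on)), function(j) covers_on(term, on[, j]), TRUE)))
  need <- seq_len(ncol(on))

  # exhaustive minimum cover selection over the prime implicants
  for (k in seq_along(all_primes)) {
    found <- list()
    combos <- utils::combn(seq_along(all_primes), k, simplify = FALSE)
    for (cb in combos) {
      if (all(need %in% unlist(coverage[cb])))
        found[[length(found) + 1L]] <- cb
    }
    if (length(found)) {
      lit_counts <- vapply(found, function(cb)
        sum(vapply(all_primes[cb], length, 1L)), 1)
      found <- found[lit_counts == min(lit_counts)]
      covers <- lapply(found, function(cb) canonical_control(new_control(all_primes[cb])))
      keys <- vapply(covers, control_key, "")
      covers <- covers[!duplicated(keys)]
      ord <- order(vapply(covers, function(f) length(f$terms), 1L),
                   vapply(covers, function(f)
                     sum(vapply(f$terms, length, 1L)), 1L),
                   vapply(covers, control_key, ""))
      return(covers[ord])
    }
  }
  pr_stop("internal error: no cover found", "petrirec_no_function_error") # nocov
}

new_creaction <- function(r, f, on, off, places) {
  structure(list(r = stats::setNames(as.integer(r), places), f = f,
                 on_states = on, off_states = off),
            class = "epn_creaction")
}

#' @export
print.epn_creaction <- function(x, ...) {
  cat(sprintf("controlled reaction: (%s)  f = %s\n",
              fmt_vec(x$r, names(x$r)), format(x$f)))
  invisible(x)
}

#' Derive all controlled reactions for a reaction vector
#'
#' The on-set is every marking (observed state or intermediate state of
#' the sequence under evaluation) at which the reaction is applied; the
#' off-set is every flagged terminal state where it is applicable.  Group
#' I reactions yield the single constant-true control; group II reactions
#' yield an empty list (the deletion reason is attached as attribute
#' `reason`); group III reactions yield one controlled reaction per
#' minimum cover from [minimize_boolean()].
#'
#' Control literals are presence/absence only; capacities above 1 combined
#' with a group III reaction are rejected.
#'
#' @param r Integer reaction vector.
#' @param on_states Matrix of application markings (columns).
#' @param terminals Matrix of flagged terminal markings (columns).
#' @param places Character vector of place names.
#' @param capacity Integer capacities.
#' @param qm_variable_cap Passed to [minimize_boolean()].
#' @return List of `epn_creaction` objects.
#' @export
derive_controls <- function(r, on_states, terminals, places,
                            capacity = 1L, qm_variable_cap = 24L) {
  group <- classify_reaction(r, on_states, terminals, capacity)
  if (group == "II") {
    out <- list()
    attr(out, "reason") <- "applied at a marking identical to an applicable terminal state"
    return(out)
  }
  applicable <- vapply(seq_len(ncol(terminals)), function(j)
    is_applicable(r, terminals[, j], capacity), TRUE)
  off <- terminals[, applicable, drop = FALSE]
  if (group == "I")
    return(list(new_creaction(r, control_true(), on_states, off, places)))
  if (any(rep_len(as.integer(capacity), length(r)) > 1L))
    pr_validation_error(paste0(
      "control derivation with capacities > 1 requires threshold logic, ",
      "which is out of scope; restrict control places to capacity 1"))
  covers <- minimize_boolean(on_states, off, places, qm_variable_cap)
  lapply(covers, function(f) new_creaction(r, f, on_states, off, places))
}

#' Translate a controlled reaction into a net fragment
#'
#' One transition per DNF term (a constant-true control yields a single
#' uncontrolled transition).  Every transition carries the standard arcs
#' realising the reaction vector (input weight = -entry, output weight =
#' +entry); each positive literal of its term becomes a read arc, each
#' negative literal an inhibitory arc.
#'
#' @param cr An `epn_creaction`.
#' @param places Character vector of all place names of the target net.
#' @param capacity Integer capacities for the fragment's places.
#' @param base_id Prefix for the generated transition ids.
#' @return An `epn` net fragment over `places`.
#' @export
to_subnet <- function(cr, places = names(cr$r), capacity = 1L, base_id = "t") {
  net <- epn_net(places, capacity)
  r <- cr$r
  consume <- -r[r < 0L]
  produce <- r[r > 0L]
  terms <- if (length(cr$f$terms)) cr$f$terms else list(stats::setNames(integer(0), character(0)))
  for (k in seq_along(terms)) {
    term <- terms[[k]]
    id <- if (length(terms) == 1L) base_id else sprintf("%s.%d", base_id, k)
    net <- add_transition(net, id,
                          consume = consume, produce = produce,
                          read = names(term)[term > 0L],
                          inhibit = names(term)[term < 0L])
  }
  net
}
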