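# Extended Petri net data model and token-game semantics.
#
# A net is a bipartite graph of places and transitions.  Standard arcs carry
# integer weights and move tokens; read arcs require at least one token in
# their place without consuming it (catalysis); inhibitory arcs require the
# place to be empty (inhibition).  Enabling is capacity-respecting on the
# output side: a firing that would push a place above its capacity is
# disabled.  This matches the applicability notion used by the
# reconstruction algorithm, and is applied uniformly in the forward token
# game (documented dialect choice).

#' Create an extended Petri net
#'
#' @param places Character vector of unique place names.  The order given
#'   here is the component ordering used by markings, reaction vectors and
#'   all reconstruction machinery; it is never alphabetised.
#' @param capacity Positive integer capacities, recycled to the number of
#'   places.  Capacity bounds both enabling (input side) and firing effects
#'   (output side).
#' @return An object of class `epn` with fields `places`, `capacity`,
#'   `transitions` and `arcs`.
#' @examples
#' net <- epn_net(c("H", "O", "W"), capacity = c(3, 1, 2))
#' net <- add_transition(net, "T", consume = c(H = 2, O = 1), produce = c(W = 2))
#' is_enabled(net, "T", c(3, 1, 0))
#' @export
epn_net <- function(places, capacity = 1L) {
  if (!is.character(places) || !length(places))
    pr_validation_error("'places' must be a non-empty character vector")
  if (anyDuplicated(places))
    pr_validation_error("place names must be unique")
  capacity <- rep_len(as.integer(capacity), length(places))
  if (any(is.na(capacity)) || any(capacity < 1L))
    pr_validation_error("capacities must be integers >= 1")
  names(capacity) <- places
  structure(list(
    places = places,
    capacity = capacity,
    transitions = character(0),
    arcs = data.frame(place = character(0), transition = character(0),
                      kind = character(0), weight = integer(0),
                      stringsAsFactors = FALSE)
  ), class = "epn")
}

arc_kinds <- c("input", "output", "read", "inhibitory")

#' Add a transition with its arcs
#'
#' @param net An `epn` object.
#' @param id Transition identifier, unique within the net.
#' @param consume,produce Named integer vectors of standard-arc weights
#'   (place -> transition and transition -> place respectively).
#' @param read,inhibit Character vectors of place names connected through
#'   read and inhibitory arcs (weight fixed to 1).
#' @return The net with the transition appended.
#' @export
add_transition <- function(net, id, consume = integer(0), produce = integer(0),
                           read = character(0), inhibit = character(0)) {
  stopifnot(inherits(net, "epn"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    pr_validation_error("transition 'id' must be a single non-empty string")
  if (id %in% net$transitions)
    pr_validation_error(sprintf("duplicate transition id '%s'", id))
  norm_weights <- function(w, what) {
    if (!length(w)) return(integer(0))
    w <- stats::setNames(as.integer(w), names(w))
    if (is.null(names(w)) || any(!nzchar(names(w))))
      pr_validation_error(sprintf("'%s' weights must be named by place", what))
    if (any(is.na(w)) || any(w < 1L))
      pr_validation_error(sprintf("'%s' weights must be integers >= 1", what))
    w
  }
  consume <- norm_weights(consume, "consume")
  produce <- norm_weights(produce, "produce")
  touched <- c(names(consume), names(produce), read, inhibit)
  unknown <- setdiff(touched, net$places)
  if (length(unknown))
    pr_validation_error(sprintf("unknown place(s): %s", paste(unknown, collapse = ", ")))
  if (anyDuplicated(names(consume)) || anyDuplicated(names(produce)) ||
      anyDuplicated(read) || anyDuplicated(inhibit))
    pr_validation_error("duplicated place within one arc kind")
  if (length(intersect(read, inhibit)))
    pr_validation_error("a place cannot carry both a read and an inhibitory arc to the same transition")
  rows <- rbind(
    if (length(consume)) data.frame(place = names(consume), transition = id,
                                    kind = "input", weight = unname(consume),
                                    stringsAsFactors = FALSE),
    if (length(produce)) data.frame(place = names(produce), transition = id,
                                    kind = "output", weight = unname(produce),
                                    stringsAsFactors = FALSE),
    if (length(read)) data.frame(place = read, transition = id,
                                 kind = "read", weight = 1L,
                                 stringsAsFactors = FALSE),
    if (length(inhibit)) data.frame(place = inhibit, transition = id,
                                    kind = "inhibitory", weight = 1L,
                                    stringsAsFactors = FALSE)
  )
  net$transitions <- c(net$transitions, id)
  net$arcs <- rbind(net$arcs, rows)
  rownames(net$arcs) <- NULL
  net
}

check_marking <- function(net, m) {
  P <- length(net$places)
  if (length(m) != P)
    pr_validation_error(sprintf("marking has length %d, expected %d", length(m), P))
  m <- as.integer(m)
  if (any(is.na(m)) || any(m < 0L) || any(m > net$capacity))
    pr_validation_error("marking outside [0, capacity]")
  names(m) <- net$places
  m
}

transition_arcs <- function(net, t) {
  if (!t %in% net$transitions)
    pr_validation_error(sprintf("unknown transition id '%s'", t))
  net$arcs[net$arcs$transition == t, , drop = FALSE]
}

#' Test whether a transition is enabled at a marking
#'
#' Enabled means: every input place holds at least the arc weight, every
#' output place can absorb the arc weight without exceeding its capacity,
#' every read-arc place holds at least one token, and every inhibitory-arc
#' place is empty.
#'
#' @param net An `epn` object.
#' @param t Transition id.
#' @param m Marking (integer vector in place order).
#' @return `TRUE` or `FALSE`.
#' @export
is_enabled <- function(net, t, m) {
  m <- check_marking(net, m)
  a <- transition_arcs(net, t)
  idx <- match(a$place, net$places)
  for (i in seq_len(nrow(a))) {
    p <- idx[i]
    ok <- switch(a$kind[i],
      input = m[p] >= a$weight[i],
      output = m[p] + a$weight[i] - input_weight(a, a$place[i]) <= net$capacity[p],
      read = m[p] >= 1L,
      inhibitory = m[p] == 0L
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

# weight consumed from a place by the same transition (0 if none); an arc
# pair input+output on one place nets out before the capacity check.
input_weight <- function(a, place) {
  w <- a$weight[a$place == place & a$kind == "input"]
  if (length(w)) w else 0L
}

#' Fire a transition
#'
#' @inheritParams is_enabled
#' @return The successor marking.  Firing a disabled transition is a
#'   contract violation and raises an error.
#' @export
fire <- function(net, t, m) {
  m <- check_marking(net, m)
  if (!is_enabled(net, t, m))
    pr_contract_error(sprintf("transition '%s' is not enabled at (%s)",
                              t, paste(m, collapse = ",")))
  m + reaction_vector(net, t)
}

#' Reaction vector of a transition
#'
#' Output weights minus input weights per place: the column of the net's
#' incidence matrix for this transition.  Read and inhibitory arcs
#' contribute zero.
#'
#' @inheritParams is_enabled
#' @return Named integer vector over the net's places.
#' @export
reaction_vector <- function(net, t) {
  a <- transition_arcs(net, t)
  r <- integer(length(net$places))
  names(r) <- net$places
  for (i in seq_len(nrow(a))) {
    if (a$kind[i] == "input") r[a$place[i]] <- r[a$place[i]] - a$weight[i]
    if (a$kind[i] == "output") r[a$place[i]] <- r[a$place[i]] + a$weight[i]
  }
  r
}

#' Incidence matrix of a net
#'
#' @param net An `epn` object.
#' @return Integer matrix, places in rows, transitions in columns.
#' @export
incidence_matrix <- function(net) {
  m <- vapply(net$transitions, function(t) reaction_vector(net, t),
              integer(length(net$places)))
  if (!length(net$transitions))
    m <- matrix(integer(0), nrow = length(net$places), ncol = 0)
  rownames(m) <- net$places
  m
}

#' Transitions enabled at a marking
#'
#' @inheritParams is_enabled
#' @return Character vector of enabled transition ids.
#' @export
enabled_transitions <- function(net, m) {
  net$transitions[vapply(net$transitions, function(t) is_enabled(net, t, m), TRUE)]
}

#' Run the token game
#'
#' Either replays an explicit firing `sequence`, or repeatedly fires the
#' enabled transition with the lexicographically smallest id (a
#' deterministic chooser used for fixtures and tests only), until the net
#' is dead or `max_steps` is reached.
#'
#' @param net An `epn` object.
#' @param m0 Initial marking.
#' @param sequence Optional character vector of transition ids to fire in
#'   order.  A disabled firing raises an error naming the step.
#' @param max_steps Step bound for the deterministic chooser.
#' @return List with `trajectory` (matrix, one marking per row),
#'   `firings` (transition ids fired) and `terminal` (`TRUE` iff the final
#'   marking enables no transition).
#' @export
simulate_net <- function(net, m0, sequence = NULL, max_steps = 1000L) {
  m <- check_marking(net, m0)
  traj <- list(m)
  fired <- character(0)
  if (!is.null(sequence)) {
    for (k in seq_along(sequence)) {
      t <- sequence[k]
      if (!t %in% net$transitions)
        pr_validation_error(sprintf("step %d: unknown transition '%s'", k, t))
      if (!is_enabled(net, t, m))
        pr_contract_error(sprintf("step %d: transition '%s' is not enabled", k, t))
      m <- fire(net, t, m)
      traj[[length(traj) + 1L]] <- m
      fired <- c(fired, t)
    }
  } else {
    for (k in seq_len(max_steps)) {
      en <- enabled_transitions(net, m)
      if (!length(en)) break
      t <- sort(en)[1L]
      m <- fire(net, t, m)
      traj[[length(traj) + 1L]] <- m
      fired <- c(fired, t)
    }
  }
  trajectory <- do.call(rbind, traj)
  colnames(trajectory) <- net$places
  rownames(trajectory) <- NULL
  list(trajectory = trajectory, firings = fired,
       terminal = length(enabled_transitions(net, m)) == 0L)
}

#' @export
print.epn <- function(x, ...) {
  cat(sprintf("Extended Petri net: %d places, %d transitions, %d arcs\n",
              length(x$places), length(x$transitions), nrow(x$arcs)))
  cat("places:", paste(x$places, collapse = ", "), "\n")
  for (t in x$transitions) {
    a <- x$arcs[x$arcs$transition == t, , drop = FALSE]
    bit <- function(kind, fmt = "%s") {
      rows <- a[a$kind == kind, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      paste(ifelse(rows$weight > 1L & kind %in% c("input", "output"),
                   sprintf("%d*%s", rows$weight, rows$place),
                   sprintf(fmt, rows$place)), collapse = " + ")
    }
    lhs <- bit("input") %||% "."
    rhs <- bit("output") %||% "."
    ctl <- c(if (!is.null(bit("read"))) sprintf("read: %s", bit("read")),
             if (!is.null(bit("inhibitory"))) sprintf("inhibit: %s", bit("inhibitory")))
    cat(sprintf("  %s: %s -> %s%s\n", t, lhs, rhs,
                if (length(ctl)) paste0("  [", paste(ctl, collapse = "; "), "]") else ""))
  }
  invisible(x)
}
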