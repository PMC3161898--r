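# Compilation of experiment tables into the state matrix and the
# difference-vector matrix.
#
# Discretisation is deliberately the caller's job: the reader rejects
# non-integer values rather than binning them.  State indices reported to
# the user are 0-based (the convention of the printed case-study tables);
# internally R's 1-based indexing is used throughout.

#' Construct an experiment
#'
#' @param values Integer matrix or data frame, one row per time point, one
#'   column per measured component (column names are the component names).
#' @param id Experiment identifier.
#' @param label Free-text description (genetic background / perturbation).
#' @param terminal Declared terminal flag for the final state: `TRUE`,
#'   `FALSE`, or `NA` to auto-detect (the series ends terminal iff its last
#'   two raw rows are identical).
#' @param time Optional numeric time stamps (defaults to 0, 1, 2, ...).
#' @return Object of class `epn_experiment`.
#' @export
experiment <- function(values, id, label = "", terminal = NA, time = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || is.null(colnames(values)))
    pr_validation_error(sprintf("experiment '%s': 'values' must be a matrix with component names", id))
  if (nrow(values) < 2L)
    pr_validation_error(sprintf("experiment '%s': at least 2 time points required", id))
  if (any(values != round(values)) || any(is.na(values)))
    pr_validation_error(sprintf(
      "experiment '%s': non-integer or missing value (discretise before input)", id))
  storage.mode(values) <- "integer"
  if (any(values < 0L))
    pr_validation_error(sprintf("experiment '%s': negative component value", id))
  time <- time %||% seq_len(nrow(values)) - 1
  if (length(time) != nrow(values))
    pr_validation_error(sprintf("experiment '%s': 'time' length mismatch", id))
  structure(list(id = as.character(id), label = label, values = values,
                 time = as.numeric(time), terminal = terminal),
            class = "epn_experiment")
}

#' Compile experiments into a state matrix
#'
#' Per experiment, consecutive duplicate measurements are collapsed
#' (compilation removes time points where nothing changed); experiments are
#' concatenated in input order and state indices run globally from 0.  The
#' last compiled state of an experiment is flagged terminal when the raw
#' series ends in a repeated, unchanging measurement, or when the
#' experiment declares `terminal = TRUE`.
#'
#' @param experiments List of [experiment()] objects sharing one component
#'   ordering.
#' @param capacity Optional named or positional integer capacities; defaults
#'   per place to the maximum value observed across all experiments (1 for
#'   boolean data).
#' @return Object of class `epn_state_matrix` with fields `components`,
#'   `capacity`, `states` (components x states integer matrix), `origin`
#'   (experiment id and within-experiment position per state), `terminal`
#'   (logical per state) and `segment` (experiment index per state).
#' @export
compile_state_matrix <- function(experiments, capacity = NULL) {
  if (inherits(experiments, "epn_experiment")) experiments <- list(experiments)
  if (!length(experiments))
    pr_validation_error("no experiments given")
  comps <- colnames(experiments[[1L]]$values)
  for (e in experiments) {
    if (!inherits(e, "epn_experiment"))
      pr_validation_error("all inputs must be 'epn_experiment' objects")
    if (!identical(colnames(e$values), comps))
      pr_validation_error(sprintf(
        "experiment '%s': component ordering differs from '%s'",
        e$id, experiments[[1L]]$id))
  }
  observed_max <- do.call(pmax, c(lapply(experiments, function(e)
    apply(e$values, 2L, max)), list(1L)))
  if (is.null(capacity)) {
    capacity <- as.integer(observed_max)
  } else {
    capacity <- rep_len(as.integer(capacity), length(comps))
  }
  names(capacity) <- comps
  cols <- list(); origin_exp <- character(0); origin_pos <- integer(0)
  terminal <- logical(0); segment <- integer(0)
  for (k in seq_along(experiments)) {
    e <- experiments[[k]]
    over <- which(t(e$values) > capacity, arr.ind = TRUE)
    if (nrow(over))
      pr_validation_error(sprintf(
        "experiment '%s': value of component '%s' at time point %d exceeds capacity %d",
        e$id, comps[over[1L, 1L]], over[1L, 2L], capacity[over[1L, 1L]]))
    keep <- c(TRUE, rowSums(abs(diff(e$values))) > 0)
    compiled <- e$values[keep, , drop = FALSE]
    n_raw <- nrow(e$values)
    repeated_end <- n_raw >= 2L &&
      all(e$values[n_raw, ] == e$values[n_raw - 1L, ])
    term_flag <- if (is.na(e$terminal)) repeated_end else isTRUE(e$terminal)
    n <- nrow(compiled)
    for (i in seq_len(n)) cols[[length(cols) + 1L]] <- compiled[i, ]
    origin_exp <- c(origin_exp, rep(e$id, n))
    origin_pos <- c(origin_pos, seq_len(n) - 1L)
    terminal <- c(terminal, c(rep(FALSE, n - 1L), term_flag))
    segment <- c(segment, rep(k, n))
  }
  states <- do.call(cbind, cols)
  rownames(states) <- comps
  colnames(states) <- as.character(seq_len(ncol(states)) - 1L)
  structure(list(components = comps, capacity = capacity, states = states,
                 origin = data.frame(experiment = origin_exp,
                                     position = origin_pos,
                                     stringsAsFactors = FALSE),
                 terminal = terminal, segment = segment),
            class = "epn_state_matrix")
}

#' @export
print.epn_state_matrix <- function(x, ...) {
  cat(sprintf("State matrix: %d components, %d states, %d experiment(s), %d terminal\n",
              length(x$components), ncol(x$states),
              length(unique(x$segment)), sum(x$terminal)))
  invisible(x)
}

#' Marking of a terminal state set
#'
#' @param sm An `epn_state_matrix`.
#' @return Integer matrix of the flagged terminal states (components in
#'   rows), possibly with zero columns.
#' @export
terminal_states <- function(sm) {
  sm$states[, sm$terminal, drop = FALSE]
}

#' Compute the difference-vector matrix
#'
#' One entry per distinct nonzero difference between consecutive states
#' within an experiment segment; the same difference observed several times
#' (also across experiments) gives a single entry whose witnesses record
#' every occurrence.  No difference is computed across experiment
#' boundaries.  Entries are ordered by first witness.
#'
#' @param sm An `epn_state_matrix` from [compile_state_matrix()].
#' @return Object of class `epn_diff_matrix`: `components`, `entries`
#'   (components x differences matrix) and `witnesses` (list of integer
#'   vectors; witness `i` means the difference carries state `i` to state
#'   `i + 1`, 0-based).
#' @export
difference_matrix <- function(sm) {
  stopifnot(inherits(sm, "epn_state_matrix"))
  entries <- list(); witnesses <- list(); keys <- character(0)
  n <- ncol(sm$states)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (sm$segment[i + 1L] != sm$segment[i]) next
    d <- sm$states[, i + 1L] - sm$states[, i]
    if (!any(d != 0L)) next
    key <- vec_key(d)
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      entries[[length(entries) + 1L]] <- d
      witnesses[[length(witnesses) + 1L]] <- i - 1L
    } else {
      witnesses[[j]] <- c(witnesses[[j]], i - 1L)
    }
  }
  mat <- if (length(entries)) do.call(cbind, entries) else
    matrix(integer(0), nrow = length(sm$components), ncol = 0)
  rownames(mat) <- sm$components
  colnames(mat) <- if (length(entries)) as.character(seq_along(entries)) else character(0)
  structure(list(components = sm$components, entries = mat,
                 witnesses = witnesses),
            class = "epn_diff_matrix")
}

#' @export
print.epn_diff_matrix <- function(x, ...) {
  cat(sprintf("Difference matrix: %d distinct difference vector(s)\n", ncol(x$entries)))
  for (j in seq_len(ncol(x$entries)))
    cat(sprintf("  d%d: %s  (witness state%s %s)\n", j,
                fmt_vec(x$entries[, j], x$components),
                if (length(x$witnesses[[j]]) > 1L) "s" else "",
                paste(x$witnesses[[j]], collapse = ", ")))
  invisible(x)
}
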