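# Internal helpers: error conditions, canonical orderings, small formatters.

`%||%` <- function(a, b) if (is.null(a)) b else a

pr_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "petrirec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pr_validation_error <- function(msg, ...) pr_stop(msg, "petrirec_validation_error", ...)
pr_contract_error   <- function(msg, ...) pr_stop(msg, "petrirec_contract_error", ...)
pr_infeasible_error <- function(msg, ...) pr_stop(msg, "petrirec_infeasible_error", ...)
pr_cap_error        <- function(msg, ...) pr_stop(msg, "petrirec_cap_error", ...)

# Lexicographic order of the rows of an integer matrix; returns a permutation.
lex_order_rows <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Canonical key for an integer vector (used to deduplicate reaction vectors).
vec_key <- function(v) paste(v, collapse = ",")

# Compact display of a signed reaction/difference vector over named places.
fmt_vec <- function(v, places) {
  nz <- which(v != 0)
  if (!length(nz)) return("0")
  paste(sprintf("%s%+d", places[nz], v[nz]), collapse = " ")
}

as_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    pr_validation_error(sprintf("'%s' must be a single non-negative number", what))
  x
}

# All distinct permutations of a multiset of indices 1..k given duplicate keys.
# Returns a list of integer vectors (indices into the original list).
multiset_permutations <- function(keys, max_permutations = Inf) {
  k <- length(keys)
  if (k == 0L) return(list())
  groups <- split(seq_len(k), keys)
  counts <- vapply(groups, length, 1L)
  total <- factorial(k) / prod(factorial(counts))
  if (total > max_permutations)
    pr_cap_error(sprintf(
      "number of orderings (%d) exceeds max_permutations (%s)",
      total, format(max_permutations)))
  res <- vector("list", total)
  n_found <- 0L
  rec <- function(remaining, acc) {
    if (!length(remaining)) {
      n_found <<- n_found + 1L
      res[[n_found]] <<- acc
      return(invisible())
    }
    seen <- character(0)
    for (i in seq_along(remaining)) {
      key <- keys[remaining[i]]
      if (key %in% seen) next
      seen <- c(seen, key)
      rec(remaining[-i], c(acc, remaining[i]))
    }
  }
  rec(seq_len(k), integer(0))
  res
}
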