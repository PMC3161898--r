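# Readers and writers for on-disk artifacts.
#
# Conventions: state indices are 0-based in every file (matching the
# running numbering of compiled state tables); component order is
# declaration order, never alphabetised; delimited text is UTF-8 with '#'
# comment lines and the separator (tab or comma) sniffed from the header;
# all writers are deterministic byte-for-byte given the same inputs.

sniff_sep <- function(path) {
  for (line in readLines(path, n = 50L, warn = FALSE)) {
    if (startsWith(line, "#") || !nzchar(trimws(line))) next
    return(if (grepl("\t", line)) "\t" else ",")
  }
  pr_validation_error(sprintf("'%s' contains no data lines", path))
}

#' Read experiments from delimited text
#'
#' Accepts one file per experiment or a single long-format file with an
#' `experiment` id column.  The header names the components; optional
#' `time` and `terminal` columns give time stamps and a declared
#' terminal flag (any `1`/`TRUE` within an experiment marks its final
#' state terminal).  Values must be integers: discretisation is the
#' caller's responsibility and non-integer values are rejected.
#'
#' @param paths Character vector of file paths.
#' @return List of [experiment()] objects.
#' @export
read_experiments <- function(paths) {
  out <- list()
  for (path in paths) {
    sep <- sniff_sep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!nrow(df)) pr_validation_error(sprintf("'%s': no data rows", path))
    meta <- intersect(c("experiment", "time", "terminal"), names(df))
    comps <- setdiff(names(df), meta)
    if (!length(comps))
      pr_validation_error(sprintf("'%s': no component columns", path))
    ids <- if ("experiment" %in% meta) as.character(df$experiment) else
      rep(tools_file_base(path), nrow(df))
    for (id in unique(ids)) {
      rows <- df[ids == id, , drop = FALSE]
      vals <- as.matrix(rows[, comps, drop = FALSE])
      if (!is.numeric(vals) || any(vals != round(vals)))
        pr_validation_error(sprintf(
          "'%s', experiment '%s': non-integer component value", path, id))
      term <- if ("terminal" %in% meta) any(rows$terminal %in% c(1, TRUE, "1", "TRUE")) else NA
      out[[length(out) + 1L]] <- experiment(
        vals, id = id, terminal = if (isTRUE(term)) TRUE else if (isFALSE(term)) NA else term,
        time = if ("time" %in% meta) rows$time else NULL)
    }
  }
  out
}

tools_file_base <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Write experiments as one long-format TSV
#'
#' @param experiments List of [experiment()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(experiments, path) {
  if (inherits(experiments, "epn_experiment")) experiments <- list(experiments)
  rows <- lapply(experiments, function(e) {
    term <- integer(nrow(e$values))
    if (isTRUE(e$terminal)) term[length(term)] <- 1L
    data.frame(experiment = e$id, time = e$time, e$values, terminal = term,
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a state matrix as TSV
#'
#' Layout mirrors the compiled case-study tables: components as rows,
#' states as 0-based columns, plus `.experiment` and `.terminal`
#' annotation rows and a `capacity` column.
#'
#' @param sm An `epn_state_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(sm, path) {
  n <- ncol(sm$states)
  header <- c("component", "capacity", as.character(seq_len(n) - 1L))
  body <- vapply(seq_along(sm$components), function(i)
    paste(c(sm$components[i], sm$capacity[i], sm$states[i, ]), collapse = "\t"), "")
  exp_row <- paste(c(".experiment", "", sm$origin$experiment), collapse = "\t")
  term_row <- paste(c(".terminal", "", as.integer(sm$terminal)), collapse = "\t")
  writeLines(c(paste(header, collapse = "\t"), body, exp_row, term_row), path)
  invisible(path)
}

#' Read a state matrix written by [write_state_matrix()]
#'
#' @param path Input file.
#' @return An `epn_state_matrix`.
#' @export
read_state_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (!identical(header[1:2], c("component", "capacity")))
    pr_validation_error(sprintf("'%s' is not a state matrix file", path))
  n <- length(header) - 2L
  rows <- cells[-1L]
  tags <- vapply(rows, `[`, "", 1L)
  comp_rows <- rows[!startsWith(tags, ".")]
  comps <- vapply(comp_rows, `[`, "", 1L)
  capacity <- as.integer(vapply(comp_rows, `[`, "", 2L))
  states <- do.call(rbind, lapply(comp_rows, function(r) as.integer(r[-(1:2)])))
  rownames(states) <- comps
  colnames(states) <- as.character(seq_len(n) - 1L)
  get_row <- function(tag) {
    r <- rows[tags == tag]
    if (!length(r)) pr_validation_error(sprintf("'%s': missing %s row", path, tag))
    r[[1L]][-(1:2)]
  }
  exps <- get_row(".experiment")
  term <- as.logical(as.integer(get_row(".terminal")))
  segment <- cumsum(c(TRUE, exps[-1L] != exps[-length(exps)]))
  position <- stats::ave(seq_along(exps), segment, FUN = seq_along) - 1L
  structure(list(components = comps,
                 capacity = stats::setNames(capacity, comps),
                 states = states,
                 origin = data.frame(experiment = exps, position = position,
                                     stringsAsFactors = FALSE),
                 terminal = term, segment = as.integer(segment)),
            class = "epn_state_matrix")
}

#' Write a difference matrix as TSV (components as rows) plus witnesses
#'
#' @param dm An `epn_diff_matrix`.
#' @param path Output file; a JSON sidecar `<path>.json` records the
#'   witnesses.
#' @return `path`, invisibly.
#' @export
write_difference_matrix <- function(dm, path) {
  k <- ncol(dm$entries)
  header <- c("component", as.character(seq_len(k)))
  body <- vapply(seq_along(dm$components), function(i)
    paste(c(dm$components[i], dm$entries[i, ]), collapse = "\t"), "")
  writeLines(c(paste(header, collapse = "\t"), body), path)
  jsonlite::write_json(
    lapply(seq_len(k), function(j) list(index = j, witnesses = dm$witnesses[[j]])),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

control_to_json <- function(f) {
  lapply(f$terms, function(term)
    lapply(seq_along(term), function(i)
      list(place = names(term)[i], polarity = unname(term[i]))))
}

control_from_json <- function(terms) {
  new_control(lapply(terms, function(term) {
    pol <- vapply(term, function(l) as.integer(l$polarity), 1L)
    stats::setNames(pol, vapply(term, function(l) l$place, ""))
  }))
}

#' Serialise a solution catalog as JSON
#'
#' Lossless for columns, alternatives, reaction vectors, control
#' functions, on/off states and witnesses; the run configuration snapshot
#' is embedded as provenance.
#'
#' @param cat An `epn_catalog`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  cols <- lapply(cat$columns, function(col) list(
    difference = unname(col$difference),
    witnesses = col$witnesses,
    alternatives = lapply(col$alternatives, function(alt) list(
      sequence_id = alt$sequence_id,
      reactions = lapply(alt$reactions, function(cr) list(
        r = unname(cr$r),
        f = control_to_json(cr$f),
        f_text = format(cr$f),
        on_states = t(unname(cr$on_states)),
        off_states = t(unname(cr$off_states))
      ))
    ))
  ))
  cfg <- cat$config
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(list(
    components = cat$components,
    capacity = unname(cat$capacity),
    terminals = t(unname(cat$terminals)),
    invariants = lapply(cat$invariants, unname),
    columns = cols,
    config = cfg
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a catalog written by [write_catalog()]
#'
#' @param path Input file.
#' @return An `epn_catalog` (without the originating state matrix).
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- unlist(x$components)
  as_marks <- function(lst) {
    m <- if (length(lst)) do.call(cbind, lapply(lst, function(col) unlist(col))) else
      matrix(integer(0), nrow = length(comps), ncol = 0L)
    rownames(m) <- comps
    m
  }
  columns <- lapply(x$columns, function(col) list(
    difference = stats::setNames(as.integer(unlist(col$difference)), comps),
    witnesses = as.integer(unlist(col$witnesses)),
    alternatives = lapply(col$alternatives, function(alt) list(
      sequence_id = alt$sequence_id,
      reactions = lapply(alt$reactions, function(cr) new_creaction(
        as.integer(unlist(cr$r)),
        control_from_json(cr$f),
        as_marks(cr$on_states), as_marks(cr$off_states), comps))
    ))
  ))
  cfg <- do.call(run_config, x$config[intersect(names(x$config),
                                                names(formals(run_config)))])
  structure(list(components = comps,
                 capacity = stats::setNames(as.integer(unlist(x$capacity)), comps),
                 terminals = as_marks(x$terminals),
                 invariants = lapply(x$invariants, function(w)
                   stats::setNames(as.integer(unlist(w)), comps)),
                 columns = columns, state_matrix = NULL, config = cfg),
            class = "epn_catalog")
}

#' Human-readable catalog table
#'
#' One block per difference-vector column listing every alternative
#' controlled-reaction sequence, mirroring the implicit tabular
#' representation of the solution space.
#'
#' @param cat An `epn_catalog`.
#' @return Character vector of lines.
#' @export
catalog_table <- function(cat) {
  out <- character(0)
  for (j in seq_along(cat$columns)) {
    col <- cat$columns[[j]]
    out <- c(out, sprintf("d%d = %s   (witness states %s)", j,
                          fmt_vec(col$difference, cat$components),
                          paste(col$witnesses, collapse = ", ")))
    for (a in seq_along(col$alternatives)) {
      alt <- col$alternatives[[a]]
      steps <- vapply(alt$reactions, function(cr)
        sprintf("(%s | f = %s)", fmt_vec(cr$r, cat$components), format(cr$f)), "")
      out <- c(out, sprintf("  alt %d: %s", a, paste(steps, collapse = " ; ")))
    }
  }
  out
}

# ---- PNML ----------------------------------------------------------------

#' Export a net as PNML
#'
#' Standard place/transition PNML; read and inhibitory arcs carry a
#' `<type><text>read|inhibitory</text></type>` annotation (a common
#' dialect, documented in the README).  Place capacities are stored as
#' `<capacity><text>` annotations.  Round-trips losslessly through
#' [import_pnml()].
#'
#' @param net An `epn` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_pnml <- function(net, path) {
  doc <- xml2::xml_new_root("pnml", xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  n <- xml2::xml_add_child(doc, "net", id = "net0",
                           type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(n, "page", id = "page0")
  for (i in seq_along(net$places)) {
    p <- xml2::xml_add_child(page, "place", id = paste0("p_", net$places[i]))
    nm <- xml2::xml_add_child(p, "name")
    xml2::xml_add_child(nm, "text", net$places[i])
    cp <- xml2::xml_add_child(p, "capacity")
    xml2::xml_add_child(cp, "text", as.character(net$capacity[i]))
  }
  for (t in net$transitions) {
    tr <- xml2::xml_add_child(page, "transition", id = paste0("t_", t))
    nm <- xml2::xml_add_child(tr, "name")
    xml2::xml_add_child(nm, "text", t)
  }
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    from <- if (a$kind[i] %in% c("input", "read", "inhibitory"))
      paste0("p_", a$place[i]) else paste0("t_", a$transition[i])
    to <- if (a$kind[i] %in% c("input", "read", "inhibitory"))
      paste0("t_", a$transition[i]) else paste0("p_", a$place[i])
    arc <- xml2::xml_add_child(page, "arc", id = paste0("a", i), source = from, target = to)
    if (a$weight[i] != 1L) {
      ins <- xml2::xml_add_child(arc, "inscription")
      xml2::xml_add_child(ins, "text", as.character(a$weight[i]))
    }
    if (a$kind[i] %in% c("read", "inhibitory")) {
      ty <- xml2::xml_add_child(arc, "type")
      xml2::xml_add_child(ty, "text", a$kind[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a PNML net
#'
#' Reads the dialect written by [export_pnml()].  Foreign arc-type
#' annotations fall back to standard arcs with a warning.
#'
#' @param path Input file.
#' @return An `epn` object.
#' @export
import_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  p_nodes <- xml2::xml_find_all(doc, ".//place")
  txt <- function(node, xp, default = NA_character_) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) default else xml2::xml_text(v)
  }
  pids <- xml2::xml_attr(p_nodes, "id")
  pnames <- vapply(seq_along(p_nodes), function(i)
    txt(p_nodes[[i]], "./name/text", sub("^p_", "", pids[i])), "")
  caps <- vapply(seq_along(p_nodes), function(i)
    as.integer(txt(p_nodes[[i]], "./capacity/text", "1")), 1L)
  t_nodes <- xml2::xml_find_all(doc, ".//transition")
  tids <- xml2::xml_attr(t_nodes, "id")
  tnames <- vapply(seq_along(t_nodes), function(i)
    txt(t_nodes[[i]], "./name/text", sub("^t_", "", tids[i])), "")
  a_nodes <- xml2::xml_find_all(doc, ".//arc")
  net <- epn_net(pnames, caps)
  # collect arcs per transition, then add transitions in document order
  spec <- lapply(tnames, function(x) list(consume = integer(0), produce = integer(0),
                                          read = character(0), inhibit = character(0)))
  names(spec) <- tids
  for (an in a_nodes) {
    src <- xml2::xml_attr(an, "source"); dst <- xml2::xml_attr(an, "target")
    w <- as.integer(txt(an, "./inscription/text", "1"))
    type <- txt(an, "./type/text", "")
    if (src %in% pids && dst %in% tids) {
      place <- pnames[match(src, pids)]
      if (type %in% c("read", "inhibitory")) {
        if (type == "read") spec[[dst]]$read <- c(spec[[dst]]$read, place)
        else spec[[dst]]$inhibit <- c(spec[[dst]]$inhibit, place)
      } else {
        if (nzchar(type) && !type %in% c("normal", "ordinary"))
          warning(sprintf("unknown arc type '%s'; treating as standard arc", type))
        spec[[dst]]$consume[place] <- w
      }
    } else if (src %in% tids && dst %in% pids) {
      place <- pnames[match(dst, pids)]
      if (nzchar(type) && !type %in% c("normal", "ordinary"))
        warning(sprintf("unknown arc type '%s' on output arc; treating as standard", type))
      spec[[src]]$produce[place] <- w
    } else {
      pr_validation_error(sprintf("arc %s -> %s does not connect a place and a transition",
                                  src, dst))
    }
  }
  for (i in seq_along(tids))
    net <- add_transition(net, tnames[i],
                          consume = spec[[tids[i]]]$consume,
                          produce = spec[[tids[i]]]$produce,
                          read = spec[[tids[i]]]$read,
                          inhibit = spec[[tids[i]]]$inhibit)
  net
}

#' Export a net in Graphviz DOT format
#'
#' Places are circles, transitions squares; read arcs are double-headed,
#' inhibitory arcs circle-headed.
#'
#' @param net An `epn` object.
#' @param path Optional output file; omit to get the DOT text.
#' @return Character vector of DOT lines (invisibly if written to file).
#' @export
export_dot <- function(net, path = NULL) {
  q <- function(x) sprintf('"%s"', x)
  lines <- c("digraph epn {", "  rankdir=LR;")
  for (p in net$places)
    lines <- c(lines, sprintf("  %s [shape=circle];", q(p)))
  for (t in net$transitions)
    lines <- c(lines, sprintf("  %s [shape=box, style=filled, fillcolor=gray85];", q(t)))
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    lab <- if (a$weight[i] != 1L) sprintf(", label=%d", a$weight[i]) else ""
    lines <- c(lines, switch(a$kind[i],
      input = sprintf("  %s -> %s [arrowhead=normal%s];", q(a$place[i]), q(a$transition[i]), lab),
      output = sprintf("  %s -> %s [arrowhead=normal%s];", q(a$transition[i]), q(a$place[i]), lab),
      read = sprintf("  %s -> %s [dir=both, arrowhead=normal, arrowtail=normal];",
                     q(a$place[i]), q(a$transition[i])),
      inhibitory = sprintf("  %s -> %s [arrowhead=odot];", q(a$place[i]), q(a$transition[i]))
    ))
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Debug dump of candidates and decompositions per difference vector
#'
#' Writes one TSV block per difference vector listing its candidate
#' reaction vectors (after invariant pruning) and all decompositions, for
#' inspection when a reconstruction surprises.
#'
#' @param sm An `epn_state_matrix`.
#' @param path Output file.
#' @param config A [run_config()] (for invariants and caps).
#' @return `path`, invisibly.
#' @export
write_decomposition_dump <- function(sm, path, config = run_config()) {
  dm <- difference_matrix(sm)
  invariants <- auto_pinvariants(sm, nominate = config$nominate,
                                 invariants = config$invariants,
                                 pairs = isTRUE(config$auto_invariants))
  lines <- character(0)
  for (j in seq_len(ncol(dm$entries))) {
    d <- dm$entries[, j]
    cands <- candidate_reactions(d, invariants, config$max_candidates)
    decs <- decompositions(d, cands, config$max_decompositions)
    lines <- c(lines,
               sprintf("# d%d\t%s", j, fmt_vec(d, sm$components)),
               sprintf("candidate\t%s",
                       vapply(cands, fmt_vec, "", places = sm$components)),
               sprintf("decomposition\t%s",
                       vapply(decs, function(parts)
                         paste(vapply(parts, fmt_vec, "", places = sm$components),
                               collapse = " + "), "")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  cfg <- config[!vapply(config, is.null, TRUE)]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- x[intersect(names(x), names(formals(run_config)))]
  fix_list <- function(v) {
    if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) v[i, ])
    else if (is.list(v)) v
    else if (is.null(v)) list()
    else list(v)
  }
  if (!is.null(x$invariants)) x$invariants <- fix_list(x$invariants)
  if (!is.null(x$nominate)) x$nominate <- fix_list(x$nominate)
  for (nm in c("max_candidates", "max_decompositions", "max_permutations"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
  do.call(run_config, x)
}
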