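engine_code <- function(engine, sc) {
  engine <- match.arg(engine, c("auto", "dijkstra", "zero_one_bfs"))
  if (engine == "auto") {
    engine <- if (sc$mismatch == 1 && sc$gap == 1) "zero_one_bfs" else "dijkstra"
  }
  if (engine == "zero_one_bfs" &&
      !(sc$mismatch %in% c(0, 1) && sc$gap %in% c(0, 1))) {
    stop("zero_one_bfs requires unit (edit-distance) costs")
  }
  c(dijkstra = 0L, zero_one_bfs = 1L)[[engine]]
}

restrict_edges <- function(g, restrict) {
  if (is.null(restrict)) return(integer())
  as.integer(restrict)
}

finish_graph_alignment <- function(g, raw, start_edge, start_offset, sub) {
  if (!isTRUE(raw$found)) {
    return(structure(list(found = FALSE, reason = raw$reason,
                          states = raw$states),
                     class = "graph_alignment"))
  }
  cols <- raw$n_match + raw$n_mismatch + raw$n_ins + raw$n_del
  structure(list(
    found = TRUE,
    cost = raw$cost,
    edges = raw$edges,
    edge_names = g$edges$name[raw$edges],
    start_offset = start_offset,
    end_edge = raw$end_edge,
    end_offset = raw$end_offset,
    query_consumed = raw$query_consumed,
    cigar = raw$cigar,
    n_match = raw$n_match, n_mismatch = raw$n_mismatch,
    n_ins = raw$n_ins, n_del = raw$n_del,
    identity = if (cols > 0) raw$n_match / cols else 1,
    states = raw$states
  ), class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  if (!x$found) {
    cat("<graph_alignment> not found (", x$reason, ")\n", sep = "")
  } else {
    cat("<graph_alignment> cost ", x$cost, ", path ",
        paste(x$edge_names, collapse = ","), ", cigar ", x$cigar, "\n",
        sep = "")
  }
  invisible(x)
}

#' Optimal path between two graph positions under a query fragment
#'
#' Finds the minimum-cost path from `<from, 0>` to `<to, |sub|>` in the
#' implicit alignment graph of `g` and `sub`: deletions and insertions cost
#' \eqn{\sigma} per base, a diagonal step costs 0 on match and \eqn{\mu}
#' otherwise, and vertex crossings are free. The returned cost equals the
#' linear-gap alignment cost of `Label(path)` against `sub`. States are
#' expanded lazily by Dijkstra, or by a 0-1 BFS over a double-ended queue
#' when both costs are 1 (edit distance); the engines are exact and agree.
#'
#' @param g an `assembly_graph`
#' @param sub query fragment (possibly empty)
#' @param from,to `graph_pos` endpoints
#' @param scoring a [scoring_scheme()]
#' @param max_states state budget; exceeding it returns a bounded-search
#'   failure (`found = FALSE`, `reason = "budget"`) that callers degrade on
#' @param engine `"auto"`, `"dijkstra"` or `"zero_one_bfs"`
#' @param restrict optional integer vector of edge ids the search may use
#' @return a `graph_alignment` (list with path, cost, cigar, identity)
#' @export
fill_between <- function(g, sub, from, to, scoring = scoring_scheme(),
                         max_states = 5e6, engine = "auto",
                         restrict = NULL) {
  pf <- check_pos(g, from)
  pt <- check_pos(g, to)
  raw <- cpp_align_fill(g$cpp, toupper(sub), pf$edge, pf$offset, pt$edge,
                        pt$offset, scoring$mismatch, scoring$gap, max_states,
                        engine_code(engine, scoring),
                        restrict_edges(g, restrict))
  finish_graph_alignment(g, raw, pf$edge, pf$offset, sub)
}

#' Extend an alignment beyond a terminal anchor
#'
#' Minimum-cost path from `<from, 0>` to any state consuming the whole
#' fragment; the graph endpoint is free (semi-global). Left extension is
#' run on the reverse-complement strand with the reversed fragment and the
#' result mapped back, so both directions share one engine.
#'
#' @inheritParams fill_between
#' @param fragment query suffix (right) or prefix (left)
#' @param from fixed `graph_pos` to extend from
#' @param direction `"right"` or `"left"`
#' @export
extend_terminal <- function(g, fragment, from, direction = c("right", "left"),
                            scoring = scoring_scheme(), max_states = 5e6,
                            engine = "auto", restrict = NULL) {
  direction <- match.arg(direction)
  p <- check_pos(g, from)
  if (direction == "right") {
    raw <- cpp_align_extend(g$cpp, toupper(fragment), p$edge, p$offset,
                            scoring$mismatch, scoring$gap, max_states,
                            engine_code(engine, scoring),
                            restrict_edges(g, restrict))
    return(finish_graph_alignment(g, raw, p$edge, p$offset, fragment))
  }
  # left: reverse-complement trick
  rc_e <- g$edges$rc[p$edge]
  rc_o <- g$edges$length[p$edge] - p$offset
  frag_rc <- revcomp(toupper(fragment))
  restrict_rc <- if (is.null(restrict)) NULL else g$edges$rc[restrict]
  raw <- cpp_align_extend(g$cpp, frag_rc, rc_e, rc_o, scoring$mismatch,
                          scoring$gap, max_states,
                          engine_code(engine, scoring),
                          restrict_edges(g, restrict_rc))
  if (!isTRUE(raw$found)) {
    return(finish_graph_alignment(g, raw, rc_e, rc_o, frag_rc))
  }
  # map the rc-strand path back to the forward strand
  edges_fwd <- rev(g$edges$rc[raw$edges])
  start_edge <- g$edges$rc[raw$end_edge]
  start_off <- g$edges$length[raw$end_edge] - raw$end_offset
  mapped <- list(
    found = TRUE, cost = raw$cost, edges = edges_fwd,
    end_edge = p$edge, end_offset = p$offset,
    query_consumed = raw$query_consumed,
    cigar = reverse_cigar(raw$cigar),
    n_match = raw$n_match, n_mismatch = raw$n_mismatch,
    n_ins = raw$n_ins, n_del = raw$n_del, states = raw$states,
    reason = ""
  )
  finish_graph_alignment(g, mapped, start_edge, start_off, fragment)
}

reverse_cigar <- function(cigar) {
  if (!nzchar(cigar)) return(cigar)
  m <- gregexpr("[0-9]+[A-Z]", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  paste(rev(parts), collapse = "")
}

#' Low-level shortest-path engines over the alignment graph
#'
#' Both engines return identical optimal costs; `zero_one_bfs` is the
#' fast path for binary-weighted (edit distance) instances and refuses
#' other schemes.
#'
#' @inheritParams fill_between
#' @param from start `graph_pos`; `to = NULL` accepts any end state
#' @param to optional target `graph_pos`
#' @export
dijkstra_product <- function(g, sub, from, to = NULL,
                             scoring = scoring_scheme(), max_states = 5e6,
                             restrict = NULL) {
  if (is.null(to)) {
    extend_terminal(g, sub, from, "right", scoring, max_states, "dijkstra",
                    restrict)
  } else {
    fill_between(g, sub, from, to, scoring, max_states, "dijkstra", restrict)
  }
}

#' @rdname dijkstra_product
#' @export
zero_one_bfs <- function(g, sub, from, to = NULL,
                         scoring = scoring_scheme(1, 1), max_states = 5e6,
                         restrict = NULL) {
  if (is.null(to)) {
    extend_terminal(g, sub, from, "right", scoring, max_states,
                    "zero_one_bfs", restrict)
  } else {
    fill_between(g, sub, from, to, scoring, max_states, "zero_one_bfs",
                 restrict)
  }
}
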