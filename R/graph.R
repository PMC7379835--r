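#' Assembly graph with oriented, labeled edges
#'
#' Builds the directed, edge-labeled graph used throughout the package from a
#' set of segments and links. Every segment contributes two directed edges
#' (`name+` and its reverse complement `name-`), so queries from either strand
#' are aligned against the same doubled graph and no special strand handling
#' is needed downstream. Links are mirrored accordingly: a link
#' `A+ -> B+` implies `B- -> A-`.
#'
#' Adjacent edges may overlap, as unitigs of a de Bruijn graph do by k-1 bp;
#' the overlap is trimmed from the successor when path labels and graph
#' distances are computed.
#'
#' @param segments named character vector of segment sequences (A/C/G/T/N), or
#'   a data frame with columns `name` and `sequence`.
#' @param links `NULL` or a data frame with columns `from`, `from_orient`
#'   (`"+"`/`"-"`), `to`, `to_orient`, `overlap` (bp).
#' @param k de Bruijn k-mer size if known (metadata used for default anchor
#'   spans); `NA` otherwise.
#' @return an object of class `assembly_graph` with tibbles `edges` and
#'   `links`.
#' @export
assembly_graph <- function(segments, links = NULL, k = NA_integer_) {
  if (is.data.frame(segments)) {
    segs <- setNames(as.character(segments$sequence), segments$name)
  } else {
    segs <- segments
    if (is.null(names(segs))) names(segs) <- paste0("s", seq_along(segs))
  }
  segs <- toupper(segs)
  if (any(nchar(segs) == 0)) stop("every segment label must be non-empty")
  bad <- grepl("[^ACGTN]", segs)
  if (any(bad)) {
    stop("segment ", names(segs)[bad][1], " contains characters outside ACGTN")
  }
  n <- length(segs)
  nm <- names(segs)
  if (anyDuplicated(nm)) stop("duplicated segment names")

  edges <- tibble(
    edge = seq_len(2L * n),
    segment = rep(nm, each = 2L),
    orient = rep(c("+", "-"), n),
    label = as.character(rbind(segs, cpp_revcomp(unname(segs)))),
    rc = as.integer(rbind(seq_len(n) * 2L, seq_len(n) * 2L - 1L))
  )
  edges$name <- paste0(edges$segment, edges$orient)
  edges$length <- nchar(edges$label)
  edges <- edges[, c("edge", "name", "segment", "orient", "label", "length", "rc")]

  eix <- setNames(edges$edge, edges$name)
  if (is.null(links) || nrow(as.data.frame(links)) == 0) {
    lk <- tibble(from = integer(), to = integer(), overlap = integer())
  } else {
    links <- as_tibble(links)
    f <- paste0(links$from, links$from_orient)
    t_ <- paste0(links$to, links$to_orient)
    flip <- function(o) ifelse(o == "+", "-", "+")
    fm <- paste0(links$to, flip(links$to_orient))
    tm <- paste0(links$from, flip(links$from_orient))
    miss <- setdiff(c(f, t_), names(eix))
    if (length(miss)) stop("link references unknown segment end: ", miss[1])
    lk <- tibble(
      from = unname(eix[c(f, fm)]),
      to = unname(eix[c(t_, tm)]),
      overlap = as.integer(rep(links$overlap, 2L))
    )
    lk <- distinct(lk)
    lens <- edges$length
    bad <- lk$overlap >= pmin(lens[lk$from], lens[lk$to])
    if (any(bad)) {
      stop("link overlap (", lk$overlap[bad][1],
           ") must be shorter than both linked segments")
    }
    lk <- arrange(lk, .data$from, .data$to)
  }

  g <- structure(
    list(edges = edges, links = lk, k = as.integer(k)),
    class = "assembly_graph"
  )
  g$cpp <- graph_cpp_view(g)
  g
}

graph_cpp_view <- function(g) {
  list(
    labels = g$edges$label,
    rc = g$edges$rc,
    link_from = g$links$from,
    link_to = g$links$to,
    link_ov = g$links$overlap
  )
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("<assembly_graph> ", nrow(x$edges) %/% 2L, " segments, ",
      nrow(x$edges), " oriented edges, ", nrow(x$links), " links, total ",
      sum(x$edges$length) %/% 2L, " bp",
      if (!is.na(x$k)) paste0(", k = ", x$k), "\n", sep = "")
  invisible(x)
}

#' One-row summary of an assembly graph
#' @param x an `assembly_graph`
#' @param ... unused
#' @export
glance.assembly_graph <- function(x, ...) {
  tibble(
    n_segments = nrow(x$edges) %/% 2L,
    n_edges = nrow(x$edges),
    n_links = nrow(x$links),
    total_bp = sum(x$edges$length) %/% 2L,
    k = x$k
  )
}

#' @export
glance <- function(x, ...) UseMethod("glance")

resolve_edge <- function(g, edge) {
  if (is.character(edge)) {
    ix <- match(edge, g$edges$name)
    if (anyNA(ix)) stop("unknown edge: ", edge[is.na(ix)][1])
    return(ix)
  }
  edge <- as.integer(edge)
  if (any(edge < 1L | edge > nrow(g$edges))) stop("edge index out of range")
  edge
}

#' A position in the graph
#'
#' A graph position is a pair of an oriented edge and an offset in
#' `[0, edge length]`; like query positions, offsets sit *between* characters.
#'
#' @param edge edge id (integer) or oriented edge name such as `"u1+"`
#' @param offset integer offset, `0 <= offset <= |edge|`
#' @export
graph_pos <- function(edge, offset) {
  structure(list(edge = edge, offset = as.integer(offset)), class = "graph_pos")
}

check_pos <- function(g, p) {
  e <- resolve_edge(g, p$edge)
  len <- g$edges$length[e]
  if (p$offset < 0L || p$offset > len) {
    stop("offset ", p$offset, " outside [0, ", len, "] on edge ",
         g$edges$name[e])
  }
  list(edge = e, offset = p$offset)
}

#' Reverse complement of nucleotide strings
#' @param x character vector of sequences
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Label of a path
#'
#' Concatenates edge labels along a path, trimming each successor's prefix by
#' the link overlap, then trims the result to the start/end offsets. The
#' label length always equals `sum(|e_i|) - sum(overlaps) - start - (|e_n| -
#' end)`.
#'
#' @param g an `assembly_graph`
#' @param edges ordered edge ids or names (consecutive edges must be linked)
#' @param start_offset,end_offset offsets on the first/last edge
#' @return nucleotide string
#' @export
label_of_path <- function(g, edges, start_offset = 0L,
                          end_offset = NULL) {
  e <- resolve_edge(g, edges)
  if (is.null(end_offset)) end_offset <- g$edges$length[e[length(e)]]
  lab <- g$edges$label[e[1]]
  if (length(e) > 1) {
    for (i in seq_len(length(e) - 1L)) {
      ov <- link_overlap(g, e[i], e[i + 1L])
      nxt <- g$edges$label[e[i + 1L]]
      lab <- paste0(lab, substr(nxt, ov + 1L, nchar(nxt)))
    }
  }
  tail_trim <- g$edges$length[e[length(e)]] - end_offset
  if (start_offset + tail_trim > nchar(lab)) {
    stop("inconsistent path: offsets trim more than the label length")
  }
  substr(lab, start_offset + 1L, nchar(lab) - tail_trim)
}

link_overlap <- function(g, from, to) {
  hit <- g$links$overlap[g$links$from == from & g$links$to == to]
  if (length(hit) == 0) {
    stop("edges ", g$edges$name[from], " and ", g$edges$name[to],
         " are not linked")
  }
  hit[1]
}

#' Minimal graph distance between two positions
#'
#' Length in bp of the shortest path (by label length) from `a` to `b`;
#' 0 when the positions coincide. The search never explores beyond `cap`
#' and returns `Inf` when no path of length `<= cap` exists.
#'
#' @param g an `assembly_graph`
#' @param a,b `graph_pos` positions
#' @param cap search cap in bp
#' @export
min_graph_distance <- function(g, a, b, cap = Inf) {
  pa <- check_pos(g, a)
  pb <- check_pos(g, b)
  stopifnot(cap >= 0)
  cpp_min_graph_distance(g$cpp, pa$edge, pa$offset, pb$edge, pb$offset, cap)
}

#' Subgraph within a radius of seed positions
#'
#' Returns the subgraph of all edges reachable within `radius` bp forward or
#' backward from any seed. Restricting an alignment to this subgraph is
#' exact whenever the optimal path fits within the radius.
#'
#' @param g an `assembly_graph`
#' @param seeds a list of `graph_pos`
#' @param radius radius in bp
#' @return an `assembly_graph` (edge ids renumbered; segment names kept)
#' @export
extract_neighborhood <- function(g, seeds, radius) {
  stopifnot(radius >= 0)
  keep <- neighborhood_edges(g, seeds, radius)
  subgraph_by_edges(g, keep)
}

# edge ids (both orientations) reachable within radius from the seeds
neighborhood_edges <- function(g, seeds, radius) {
  if (inherits(seeds, "graph_pos")) seeds <- list(seeds)
  ps <- lapply(seeds, function(p) check_pos(g, p))
  se <- vapply(ps, `[[`, integer(1), "edge")
  so <- vapply(ps, `[[`, integer(1), "offset")
  fwd <- cpp_reach_forward(g$cpp, se, so, radius)
  rc <- g$edges$rc
  bwd <- cpp_reach_forward(g$cpp, rc[se], g$edges$length[se] - so, radius)
  sort(unique(c(fwd, rc[bwd])))
}

subgraph_by_edges <- function(g, keep) {
  keep <- sort(unique(c(keep, g$edges$rc[keep])))
  segs <- unique(g$edges$segment[keep])
  sel <- g$edges[g$edges$segment %in% segs & g$edges$orient == "+", ]
  lk <- g$links[g$links$from %in% keep & g$links$to %in% keep, ]
  links <- tibble(
    from = g$edges$segment[lk$from],
    from_orient = g$edges$orient[lk$from],
    to = g$edges$segment[lk$to],
    to_orient = g$edges$orient[lk$to],
    overlap = lk$overlap
  )
  assembly_graph(setNames(sel$label, sel$segment), links, k = g$k)
}
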