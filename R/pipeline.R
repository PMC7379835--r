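# 0-based half-open substring helper; matches the coordinate convention used
# for anchors and graph positions (positions sit between characters)
substr0 <- function(s, a, b) {
  if (b <= a) return("")
  substr(s, a + 1L, b)
}

empty_alignment_tbl <- function() {
  tibble(
    query = character(), qstart = integer(), qend = integer(),
    qlen = integer(), start_edge = character(), start_offset = integer(),
    end_edge = character(), end_offset = integer(), path = character(),
    path_length = integer(), path_full_length = integer(), cost = numeric(),
    identity = numeric(), mapped = logical(), cigar = character(),
    n_match = integer(), n_mismatch = integer(), n_ins = integer(),
    n_del = integer(), n_anchors = integer()
  )
}

collapse_edges <- function(pieces) {
  e <- unlist(pieces)
  if (length(e) == 0) return(e)
  e[c(TRUE, e[-1] != e[-length(e)])]
}

# adaptive banded global alignment of query fragment vs path label
banded_global <- function(qsub, lab, sc) {
  la <- nchar(qsub); lb <- nchar(lab)
  if (la == 0 && lb == 0) {
    return(list(found = TRUE, cost = 0, cigar = "", n_match = 0L,
                n_mismatch = 0L, n_ins = 0L, n_del = 0L))
  }
  stopifnot(sc$gap > 0)
  band <- max(32L, 16L + abs(la - lb))
  repeat {
    nw <- cpp_nw_band(qsub, lab, sc$mismatch, sc$gap, band)
    full <- band >= la + lb
    if ((isTRUE(nw$found) && nw$cost <= band * sc$gap) || full) return(nw)
    band <- band * 2L
  }
}

parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) {
    return(data.frame(len = integer(), op = character()))
  }
  parts <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z]$", "", parts)),
             op = sub("^[0-9]+", "", parts))
}

cigar_string <- function(runs) {
  if (nrow(runs) == 0) return("")
  paste0(runs$len, runs$op, collapse = "")
}

#' Align one nucleotide query to the graph
#'
#' The full pipeline: anchor search, anchor filtering, heaviest-chain
#' selection, then shortest-path reconstruction of the filling paths between
#' consecutive skeleton anchors and of the terminal extensions beyond the
#' outermost anchors. The stitched path is re-scored end-to-end against the
#' query (banded global alignment), so anchor-interior mismatches are
#' reflected in the final cigar and identity. Queries with no surviving
#' anchors are reported unaligned (zero rows). If a filling path cannot be
#' found within the search limits the pipeline keeps the largest contiguous
#' part of the skeleton and reports reduced query coverage.
#'
#' @param g an `assembly_graph`
#' @param query nucleotide sequence
#' @param name query name for the output
#' @param k_seed,min_span,max_gap,max_occ see [find_anchors()]
#' @param t_min,T_mid see [filter_anchors()]
#' @param alpha see [compatible_anchors()]
#' @param scoring a [scoring_scheme()]; the default is edit distance
#' @param max_states per-subtask state budget for the path searches
#' @param mapped_frac a query counts as mapped when at least this fraction
#'   of its length is covered by a single alignment path (default 0.8)
#' @return tibble with one row per alignment (zero rows when unaligned)
#' @export
align_nt_query <- function(g, query, name = "query", k_seed = 14L,
                           min_span = NULL, max_gap = 150L, max_occ = 500L,
                           t_min = 200L, T_mid = 500L, alpha = 1.3,
                           scoring = scoring_scheme(1, 1), max_states = 5e6,
                           mapped_frac = 0.8) {
  query <- toupper(query)
  qlen <- nchar(query)
  anchors <- find_anchors(g, query, k_seed, min_span, max_gap, max_occ)
  anchors <- filter_anchors(anchors, qlen, g, T_mid, t_min)
  if (nrow(anchors) == 0) return(empty_alignment_tbl())
  ch <- heaviest_chain(g, anchors, alpha)
  a <- ch$anchors
  n <- nrow(a)

  # filling paths between consecutive skeleton anchors
  fills <- vector("list", if (n > 1) n - 1 else 0)
  ok <- logical(length(fills))
  for (i in seq_len(max(0, n - 1))) {
    sub <- substr0(query, a$qe[i], a$qs[i + 1])
    p1 <- graph_pos(a$edge[i], a$ee[i])
    p2 <- graph_pos(a$edge[i + 1], a$es[i + 1])
    nb <- neighborhood_edges(g, list(p1, p2),
                             ceiling(alpha * nchar(sub)) + 2 * t_min)
    f <- fill_between(g, sub, p1, p2, scoring, max_states,
                      engine = "auto", restrict = nb)
    fills[[i]] <- f
    ok[i] <- isTRUE(f$found)
  }

  # keep the largest contiguous run of anchors whose fills all succeeded
  run_id <- cumsum(c(0L, !ok))[seq_len(n)]
  spans <- vapply(split(seq_len(n), run_id), function(ix) {
    a$qe[ix[length(ix)]] - a$qs[ix[1]]
  }, numeric(1))
  pick <- split(seq_len(n), run_id)[[which.max(spans)]]
  first <- pick[1]; last <- pick[length(pick)]

  # terminal extensions
  left_frag <- substr0(query, 0L, a$qs[first])
  right_frag <- substr0(query, a$qe[last], qlen)
  left <- NULL
  if (nzchar(left_frag)) {
    p <- graph_pos(a$edge[first], a$es[first])
    nb <- neighborhood_edges(g, list(p),
                             ceiling(alpha * nchar(left_frag)) + 2 * t_min)
    cand <- extend_terminal(g, left_frag, p, "left", scoring, max_states,
                            engine = "auto", restrict = nb)
    if (isTRUE(cand$found)) left <- cand
  }
  right <- NULL
  if (nzchar(right_frag)) {
    p <- graph_pos(a$edge[last], a$ee[last])
    nb <- neighborhood_edges(g, list(p),
                             ceiling(alpha * nchar(right_frag)) + 2 * t_min)
    cand <- extend_terminal(g, right_frag, p, "right", scoring, max_states,
                            engine = "auto", restrict = nb)
    if (isTRUE(cand$found)) right <- cand
  }

  qstart <- if (is.null(left)) a$qs[first] else 0L
  qend <- if (is.null(right)) a$qe[last] else qlen
  start_edge <- if (is.null(left)) a$edge[first] else left$edges[1]
  start_off <- if (is.null(left)) a$es[first] else left$start_offset
  end_edge <- if (is.null(right)) a$edge[last] else right$end_edge
  end_off <- if (is.null(right)) a$ee[last] else right$end_offset

  pieces <- list(if (!is.null(left)) left$edges)
  for (i in seq(first, last)) {
    pieces <- c(pieces, list(a$edge[i]))
    if (i < last) pieces <- c(pieces, list(fills[[i]]$edges))
  }
  pieces <- c(pieces, list(if (!is.null(right)) right$edges))
  path_edges <- collapse_edges(pieces)

  lab <- label_of_path(g, path_edges, start_off, end_off)
  nw <- banded_global(substr0(query, qstart, qend), lab, scoring)

  # trim terminal pure-insertion runs: query tails consumed off the end of
  # the path carry no graph alignment and should not count as coverage
  runs <- parse_cigar(nw$cigar)
  cost <- nw$cost
  n_ins <- nw$n_ins
  while (nrow(runs) > 0 && runs$op[1] == "I") {
    qstart <- qstart + runs$len[1]
    cost <- cost - runs$len[1] * scoring$gap
    n_ins <- n_ins - runs$len[1]
    runs <- runs[-1, , drop = FALSE]
  }
  while (nrow(runs) > 0 && runs$op[nrow(runs)] == "I") {
    qend <- qend - runs$len[nrow(runs)]
    cost <- cost - runs$len[nrow(runs)] * scoring$gap
    n_ins <- n_ins - runs$len[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  cols <- nw$n_match + nw$n_mismatch + n_ins + nw$n_del
  full_len <- nchar(label_of_path(g, path_edges, 0L, NULL))

  tibble(
    query = name, qstart = qstart, qend = qend, qlen = qlen,
    start_edge = g$edges$name[start_edge], start_offset = start_off,
    end_edge = g$edges$name[end_edge], end_offset = end_off,
    path = paste(g$edges$name[path_edges], collapse = ","),
    path_length = nchar(lab), path_full_length = full_len,
    cost = cost,
    identity = if (cols > 0) nw$n_match / cols else 1,
    mapped = (qend - qstart) >= mapped_frac * qlen,
    cigar = cigar_string(runs),
    n_match = nw$n_match, n_mismatch = nw$n_mismatch, n_ins = n_ins,
    n_del = nw$n_del, n_anchors = length(pick)
  )
}

#' Align many nucleotide queries
#'
#' @param g an `assembly_graph`
#' @param queries named character vector of sequences, or a FASTA/FASTQ path
#' @param ... passed to [align_nt_query()]
#' @return tibble, one row per aligned query (unaligned queries are absent)
#' @export
align_nt <- function(g, queries, ...) {
  if (length(queries) == 1 && is.character(queries) &&
      is.null(names(queries)) && file.exists(queries)) {
    queries <- read_seqs(queries)
  }
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  rows <- purrr::imap(queries, function(s, nm) align_nt_query(g, s, nm, ...))
  bind_rows(c(list(empty_alignment_tbl()), rows))
}

#' Mapping and identity metrics
#'
#' A read is considered mapped when at least `threshold` (default 80%) of
#' its length is covered by a single alignment path; identity is the
#' fraction of matching columns in the alignment.
#'
#' @param aln alignment tibble from [align_nt()]
#' @param threshold mapped-coverage threshold
#' @export
is_mapped <- function(aln, threshold = 0.8) {
  (aln$qend - aln$qstart) >= threshold * aln$qlen
}

#' @rdname is_mapped
#' @export
alignment_identity <- function(aln) {
  cols <- aln$n_match + aln$n_mismatch + aln$n_ins + aln$n_del
  ifelse(cols > 0, aln$n_match / cols, 1)
}

#' Per-run alignment summary
#'
#' Counts queries, mapped queries (longest continuous alignment per query)
#' and the mean identity across the longest continuous alignments of the
#' mapped queries.
#'
#' @param aln alignment tibble
#' @param n_queries total number of queries attempted (unaligned ones are
#'   not present in `aln`)
#' @param threshold mapped-coverage threshold
#' @export
summarise_alignments <- function(aln, n_queries = NULL, threshold = 0.8) {
  if (is.null(n_queries)) n_queries <- length(unique(aln$query))
  if (nrow(aln) == 0) {
    return(tibble(n_queries = n_queries, n_aligned = 0L, n_mapped = 0L,
                  mapped_pct = 0, mean_identity = NA_real_))
  }
  per_query <- aln %>%
    group_by(.data$query) %>%
    filter(.data$qend - .data$qstart == max(.data$qend - .data$qstart)) %>%
    dplyr::slice(1) %>%
    ungroup()
  mapped <- is_mapped(per_query, threshold)
  tibble(
    n_queries = n_queries,
    n_aligned = nrow(per_query),
    n_mapped = sum(mapped),
    mapped_pct = 100 * sum(mapped) / max(1L, n_queries),
    mean_identity = if (any(mapped)) mean(per_query$identity[mapped]) else NA_real_
  )
}
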