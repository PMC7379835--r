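anchor_tibble <- function(g, edge, qs, qe, es, ee, frame = NULL) {
  out <- tibble(
    edge = as.integer(edge),
    edge_name = g$edges$name[as.integer(edge)],
    qs = as.integer(qs), qe = as.integer(qe),
    es = as.integer(es), ee = as.integer(ee)
  )
  out$span <- out$qe - out$qs
  out$weight <- as.numeric(out$span)
  if (!is.null(frame)) out$frame <- as.integer(frame)
  out
}

#' Find anchor alignments between a query and edge labels
#'
#' Anchors are local high-identity matches between a range on the query and a
#' range on a single edge. The internal seeder finds exact k-mer matches
#' (default seed size 14 bp), merges co-diagonal seeds into maximal exact
#' runs, and chains nearby colinear runs (bounded gap and diagonal drift)
#' into gapped anchors, so that a read with scattered errors still produces
#' one long anchor per edge. An exact occurrence of a query substring of
#' length `>= k_seed` always yields an anchor covering it (subject to
#' `min_span`). Results are deterministic and sorted by (query start,
#' edge id).
#'
#' Anchors may also be imported from PAF via [read_paf_anchors()]; both
#' sources feed [filter_anchors()] identically.
#'
#' @param g an `assembly_graph`
#' @param query nucleotide query string
#' @param k_seed exact seed length in bp
#' @param min_span minimum anchor span on the query; defaults to the graph's
#'   de Bruijn k when known, else `k_seed`
#' @param max_gap largest seed-to-seed gap merged into one anchor (bp)
#' @param max_occ ignore query k-mers occurring more often than this
#' @return anchor tibble with 0-based half-open ranges `[qs,qe)` on the
#'   query and `[es,ee)` on the edge; `span = qe - qs`; `weight = span`
#' @export
find_anchors <- function(g, query, k_seed = 14L, min_span = NULL,
                         max_gap = 150L, max_occ = 500L) {
  stopifnot(nzchar(query))
  if (is.null(min_span)) {
    min_span <- if (!is.na(g$k)) g$k else k_seed
  }
  m <- cpp_find_anchors(g$cpp, toupper(query), as.integer(k_seed),
                        as.integer(max(min_span, k_seed)),
                        as.integer(max_gap), as.integer(max_occ))
  anchor_tibble(g, m[, "edge"], m[, "qs"], m[, "qe"], m[, "es"], m[, "ee"])
}

#' Filter unreliable and ambiguous anchors
#'
#' Applies three discard rules in order:
#'
#' 1. anchors "in the middle" of long edges that span less than `T_mid` bp:
#'    discard `a` when
#'    `(ee-es) + min(qs, es) + min(qlen - qe, |e| - ee) > 3 * (ee - es)`
#'    and `span < T_mid`;
#' 2. anchors at least half of whose query range is covered by other
#'    anchors. Mutually covering sets are resolved by a worst-first sweep
#'    (ascending span, descending edge id), re-checking coverage against the
#'    anchors not yet discarded, so that exactly one representative of a
#'    symmetric pair survives — the one with the largest span, ties to the
#'    smallest edge id;
#' 3. anchors spanning less than `t_min` bp.
#'
#' The filter is idempotent and survivors keep their input order.
#'
#' @param anchors anchor tibble
#' @param query_len query length in bp
#' @param g an `assembly_graph`
#' @param T_mid span threshold for the mid-edge rule (default 500 bp)
#' @param t_min minimum surviving span (default 200 bp)
#' @export
filter_anchors <- function(anchors, query_len, g, T_mid = 500L,
                           t_min = 200L) {
  if (nrow(anchors) == 0) return(anchors)
  a <- anchors
  elen <- g$edges$length[a$edge]

  # rule 1: mid-edge anchors below T_mid
  lhs <- (a$ee - a$es) + pmin(a$qs, a$es) +
    pmin(query_len - a$qe, elen - a$ee)
  keep1 <- !(lhs > 3 * (a$ee - a$es) & a$span < T_mid)
  a <- a[keep1, , drop = FALSE]
  if (nrow(a) == 0) return(a)

  # rule 2: half-covered query ranges, worst-first sweep
  ord <- order(a$span, -a$edge, -a$qs)  # ascending priority
  alive <- rep(TRUE, nrow(a))
  for (i in ord) {
    others <- which(alive)
    others <- others[others != i]
    if (length(others) == 0) next
    cov <- covered_length(a$qs[i], a$qe[i], a$qs[others], a$qe[others])
    if (cov * 2 >= a$span[i]) alive[i] <- FALSE
  }
  a <- a[alive, , drop = FALSE]
  if (nrow(a) == 0) return(a)

  # rule 3: short anchors
  a[a$span >= t_min, , drop = FALSE]
}

# total length of [s, e) covered by the union of [ss_i, ee_i)
covered_length <- function(s, e, ss, ee) {
  ss <- pmax(ss, s)
  ee <- pmin(ee, e)
  keep <- ss < ee
  if (!any(keep)) return(0L)
  ss <- ss[keep]; ee <- ee[keep]
  o <- order(ss)
  ss <- ss[o]; ee <- ee[o]
  tot <- 0L
  cur_s <- ss[1]; cur_e <- ee[1]
  for (i in seq_along(ss)[-1]) {
    if (ss[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- ss[i]; cur_e <- ee[i]
    } else {
      cur_e <- max(cur_e, ee[i])
    }
  }
  tot + (cur_e - cur_s)
}
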