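#' Find protein anchors on six-frame translated edge labels
#'
#' Edge labels are translated in all three frames (the reverse strand is
#' covered by the `-` edges of the doubled graph) and ungapped exact
#' amino-acid runs against the query are reported. This mirrors anchor
#' search on canonical nucleotide representations with an infinite gap-open
#' penalty: ungapped, frame-consistent matches only. Anchors shorter than
#' `min_len` nucleotides are discarded.
#'
#' @param g an `assembly_graph`
#' @param query protein sequence (one-letter code, no stops)
#' @param min_len minimum anchor length in nucleotides; defaults to the
#'   graph k, with a floor of 15 (5 codons)
#' @return anchor tibble with residue query ranges `[qs,qe)`, nucleotide
#'   edge ranges `[es,ee)`, `frame` (0-2) and `span` in nucleotides
#' @export
find_aa_anchors <- function(g, query, min_len = NULL) {
  query <- toupper(query)
  stopifnot(nzchar(query))
  if (grepl("\\*", query)) stop("protein query contains a stop character")
  if (is.null(min_len)) min_len <- max(if (!is.na(g$k)) g$k else 0L, 15L)
  min_res <- as.integer(ceiling(min_len / 3))
  out <- list()
  for (e in seq_len(nrow(g$edges))) {
    lab <- g$edges$label[e]
    len <- nchar(lab)
    for (f in 0:2) {
      nres <- (len - f) %/% 3
      if (nres < min_res) next
      tr <- cpp_translate(substr(lab, f + 1L, f + 3L * nres))
      runs <- cpp_exact_aa_runs(query, tr, min_res)
      if (nrow(runs) == 0) next
      out[[length(out) + 1]] <- anchor_tibble(
        g, e,
        qs = runs[, "qs"], qe = runs[, "qe"],
        es = f + 3L * runs[, "ts"],
        ee = f + 3L * (runs[, "ts"] + (runs[, "qe"] - runs[, "qs"])),
        frame = f
      )
    }
  }
  if (length(out) == 0) {
    a <- anchor_tibble(g, integer(), integer(), integer(), integer(),
                       integer(), frame = integer())
  } else {
    a <- distinct(bind_rows(out))
  }
  # protein anchor spans are measured in nucleotides
  a$span <- 3L * (a$qe - a$qs)
  a$weight <- as.numeric(a$span)
  arrange(a, .data$qs, .data$edge, .data$es)
}

finish_aa_alignment <- function(g, raw, sc, fragment_len) {
  if (!isTRUE(raw$found)) {
    return(structure(list(found = FALSE, reason = raw$reason,
                          states = raw$states),
                     class = "aa_graph_alignment"))
  }
  sg_weight <- raw$weight - fragment_len * sc$shift
  structure(list(
    found = TRUE,
    weight = raw$weight,          # shifted (SG') weight
    sg_weight = sg_weight,        # un-shifted alignment-graph weight
    score = -sg_weight,           # matrix score of the extension
    edges = raw$edges,
    edge_names = g$edges$name[raw$edges],
    end_edge = raw$end_edge, end_offset = raw$end_offset,
    n_res = raw$n_res, n_del_codons = raw$n_del_codons, n_ins = raw$n_ins,
    nt_consumed = raw$nt_consumed,
    states = raw$states
  ), class = "aa_graph_alignment")
}

#' Extend a protein alignment from a codon boundary
#'
#' Shortest-path search in the shifted frame-state alignment graph from
#' `<from, 0, eps>` to any state that has consumed the whole fragment with
#' an empty frame state. Codons are accumulated base by base and may span
#' edges; codon deletions cost \eqn{\sigma}; consuming a residue costs
#' `C - M[translated codon, residue]`; insertions (cost `C + sigma`) occur
#' only between codons; completed stop codons are forbidden, so every
#' returned path is an AA-path. Left extensions run on the
#' reverse-complement strand with the reversed fragment, completed codons
#' being reverse-complemented before translation.
#'
#' @param g an `assembly_graph`
#' @param fragment protein fragment to align
#' @param from `graph_pos` on a codon boundary of the anchor's frame
#' @param direction `"right"` or `"left"`
#' @param scoring an [aa_scoring_scheme()]
#' @param max_states state budget
#' @param restrict optional edge-id restriction
#' @param to optional `graph_pos` target (global-style extension, mainly for
#'   validation against string aligners)
#' @param allow_stop_deletion permit *deleted* codons to be stops
#'   (pseudo-gene hunting; off by default)
#' @return an `aa_graph_alignment`: shifted weight, un-shifted weight,
#'   extension score, path and frame bookkeeping counts
#' @export
extend_aa <- function(g, fragment, from, direction = c("right", "left"),
                      scoring = aa_scoring_scheme(), max_states = 5e6,
                      restrict = NULL, to = NULL,
                      allow_stop_deletion = FALSE) {
  direction <- match.arg(direction)
  fragment <- toupper(fragment)
  p <- check_pos(g, from)
  sc <- scoring
  if (direction == "right") {
    te <- -1L; to_off <- -1L
    if (!is.null(to)) {
      pt <- check_pos(g, to)
      te <- pt$edge; to_off <- pt$offset
    }
    raw <- cpp_align_aa(g$cpp, fragment, p$edge, p$offset, te, to_off,
                        sc$matrix, sc$alphabet, sc$gap, sc$shift, FALSE,
                        allow_stop_deletion, max_states,
                        restrict_edges(g, restrict))
    return(finish_aa_alignment(g, raw, sc, nchar(fragment)))
  }
  # left extension on the reverse-complement strand
  rc_e <- g$edges$rc[p$edge]
  rc_o <- g$edges$length[p$edge] - p$offset
  frag_rev <- paste(rev(strsplit(fragment, "")[[1]]), collapse = "")
  restrict_rc <- if (is.null(restrict)) NULL else g$edges$rc[restrict]
  te <- -1L; to_off <- -1L
  if (!is.null(to)) {
    pt <- check_pos(g, to)
    te <- g$edges$rc[pt$edge]
    to_off <- g$edges$length[pt$edge] - pt$offset
  }
  raw <- cpp_align_aa(g$cpp, frag_rev, rc_e, rc_o, te, to_off,
                      sc$matrix, sc$alphabet, sc$gap, sc$shift, TRUE,
                      allow_stop_deletion, max_states,
                      restrict_edges(g, restrict_rc))
  res <- finish_aa_alignment(g, raw, sc, nchar(fragment))
  if (!isTRUE(res$found)) return(res)
  # map back to the forward strand
  res$edges <- rev(g$edges$rc[raw$edges])
  res$edge_names <- g$edges$name[res$edges]
  res$start_edge <- g$edges$rc[raw$end_edge]
  res$start_offset <- g$edges$length[raw$end_edge] - raw$end_offset
  res$end_edge <- p$edge
  res$end_offset <- p$offset
  res
}

empty_protein_tbl <- function() {
  tibble(
    query = character(), score = numeric(), coverage = numeric(),
    identity = numeric(), path = character(), path_length = integer(),
    frame = integer(), start_edge = character(), start_offset = integer(),
    end_edge = character(), end_offset = integer(), translated = character(),
    score_raw = numeric(), n_anchor_res = integer()
  )
}

#' Align a protein query to the nucleotide graph
#'
#' For every surviving anchor the query is extended left and right through
#' the frame-state alignment graph (no chaining: protein queries are short
#' enough that single-anchor extension is both simpler and more accurate,
#' and it avoids coordinating reading frames across anchors). Paths
#' covering less than `coverage_min` of the query coding length are
#' dropped, identical paths are deduplicated, and each surviving path is
#' translated and re-scored against the query with a standard global
#' protein aligner (linear gap \eqn{\sigma}, same matrix); results are
#' sorted by that score.
#'
#' @param g an `assembly_graph`
#' @param query protein sequence
#' @param name query name
#' @param scoring an [aa_scoring_scheme()] (BLOSUM90, \eqn{\sigma = 5})
#' @param min_anchor see [find_aa_anchors()]
#' @param coverage_min minimum fraction of the query coding length a path
#'   must span (default 0.8)
#' @param max_states state budget per extension
#' @param allow_stop_deletion see [extend_aa()]
#' @return tibble, best alignment first; `coverage` is path length over
#'   `3 * nchar(query)`, `identity` the amino-acid identity of the global
#'   re-alignment
#' @export
align_protein <- function(g, query, name = "query",
                          scoring = aa_scoring_scheme(), min_anchor = NULL,
                          coverage_min = 0.8, max_states = 5e6,
                          allow_stop_deletion = FALSE) {
  query <- toupper(query)
  qlen <- nchar(query)
  anchors <- find_aa_anchors(g, query, min_anchor)
  if (nrow(anchors) == 0) return(empty_protein_tbl())
  sc <- scoring
  aa_idx <- function(res) match(res, strsplit(sc$alphabet, "")[[1]])
  qres <- strsplit(query, "")[[1]]

  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    an <- anchors[i, ]
    left_frag <- substr0(query, 0L, an$qs)
    right_frag <- substr0(query, an$qe, qlen)
    radius <- function(frag) ceiling(3.9 * nchar(frag)) + 200

    left <- NULL
    if (nzchar(left_frag)) {
      p <- graph_pos(an$edge, an$es)
      nb <- neighborhood_edges(g, list(p), radius(left_frag))
      cand <- extend_aa(g, left_frag, p, "left", sc, max_states, restrict = nb,
                        allow_stop_deletion = allow_stop_deletion)
      if (!isTRUE(cand$found)) next
      left <- cand
    }
    right <- NULL
    if (nzchar(right_frag)) {
      p <- graph_pos(an$edge, an$ee)
      nb <- neighborhood_edges(g, list(p), radius(right_frag))
      cand <- extend_aa(g, right_frag, p, "right", sc, max_states,
                        restrict = nb,
                        allow_stop_deletion = allow_stop_deletion)
      if (!isTRUE(cand$found)) next
      right <- cand
    }

    start_edge <- if (is.null(left)) an$edge else left$start_edge
    start_off <- if (is.null(left)) an$es else left$start_offset
    end_edge <- if (is.null(right)) an$edge else right$end_edge
    end_off <- if (is.null(right)) an$ee else right$end_offset
    path_edges <- collapse_edges(list(
      if (!is.null(left)) left$edges, an$edge,
      if (!is.null(right)) right$edges))

    lab <- label_of_path(g, path_edges, start_off, end_off)
    if (nchar(lab) %% 3 != 0) {
      stop("internal: protein path length not divisible by 3")
    }
    coverage <- nchar(lab) / (3 * qlen)
    if (coverage < coverage_min) next
    translated <- cpp_translate(lab)
    if (grepl("\\*", translated)) {
      stop("internal: stop codon in a returned AA-path")
    }

    anchor_res <- qres[seq(an$qs + 1L, an$qe)]
    ix <- aa_idx(anchor_res)
    anchor_score <- sum(sc$matrix[cbind(ix, ix)])
    score_raw <- anchor_score +
      (if (is.null(left)) 0 else left$score) +
      (if (is.null(right)) 0 else right$score)

    rows[[length(rows) + 1]] <- tibble(
      query = name, score = NA_real_, coverage = coverage,
      identity = NA_real_,
      path = paste(g$edges$name[path_edges], collapse = ","),
      path_length = nchar(lab),
      frame = as.integer(start_off %% 3),
      start_edge = g$edges$name[start_edge], start_offset = start_off,
      end_edge = g$edges$name[end_edge], end_offset = end_off,
      translated = translated, score_raw = score_raw,
      n_anchor_res = an$qe - an$qs
    )
  }
  if (length(rows) == 0) return(empty_protein_tbl())
  res <- distinct(bind_rows(rows),
                  .data$path, .data$start_offset, .data$end_offset,
                  .keep_all = TRUE)

  # translate + re-score against the query with a standard global aligner
  resc <- purrr::map(res$translated, function(tr) rescore_protein(query, tr, sc))
  res$score <- vapply(resc, `[[`, numeric(1), "score")
  res$identity <- vapply(resc, `[[`, numeric(1), "identity")
  arrange(res, desc(.data$score))
}

rescore_protein <- function(query, translated, sc) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(translated),
    substitutionMatrix = sc$matrix, gapOpening = 0, gapExtension = sc$gap,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(
    score = Biostrings::score(aln),
    identity = sum(p == s & p != "-") / length(p)
  )
}
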