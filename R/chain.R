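#' Compatibility of two anchors
#'
#' Anchor `b` must follow `a` on the query without overlap
#' (`qe(a) <= qs(b)`), and the minimal graph distance from the end position
#' of `a` to the start position of `b` must not significantly exceed the
#' query gap: `dist_G <= alpha * (qs(b) - qe(a))`, with `alpha = 1.3` by
#' default. A zero query gap requires zero graph distance. The distance
#' query is capped at `alpha * gap`, which is enough to decide the
#' predicate.
#'
#' @param g an `assembly_graph`
#' @param a,b single anchors (one-row tibbles or lists with fields `edge`,
#'   `qs`, `qe`, `es`, `ee`)
#' @param alpha graph-vs-query gap stretch tolerance
#' @export
compatible_anchors <- function(g, a, b, alpha = 1.3) {
  if (b$qs < a$qe) return(FALSE)
  gap <- b$qs - a$qe
  d <- min_graph_distance(g, graph_pos(a$edge, a$ee), graph_pos(b$edge, b$es),
                          cap = alpha * gap)
  is.finite(d) && d <= alpha * gap
}

#' Heaviest chain of compatible anchors
#'
#' Dynamic program over anchors sorted by query start: the chain maximizing
#' total span (anchor weight) over all chains whose consecutive pairs are
#' compatible. Ties are broken towards the smaller total graph distance,
#' then the lexicographically smallest index sequence, making the result
#' deterministic. The selected chain is the skeleton of the final
#' alignment.
#'
#' @param g an `assembly_graph`
#' @param anchors anchor tibble (normally already filtered)
#' @param alpha see [compatible_anchors()]
#' @return an object of class `sga_chain`: list with `anchors` (ordered
#'   tibble) and `total_weight`
#' @export
heaviest_chain <- function(g, anchors, alpha = 1.3) {
  if (nrow(anchors) == 0) {
    return(structure(list(anchors = anchors, total_weight = 0),
                     class = "sga_chain"))
  }
  a <- arrange(anchors, .data$qs, .data$edge, .data$es)
  n <- nrow(a)
  best <- a$weight            # best chain weight ending at i
  bdist <- rep(0, n)          # its total graph distance
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || a$qe[j] > a$qs[i]) next
      gap <- a$qs[i] - a$qe[j]
      d <- min_graph_distance(g, graph_pos(a$edge[j], a$ee[j]),
                              graph_pos(a$edge[i], a$es[i]),
                              cap = alpha * gap)
      if (!is.finite(d) || d > alpha * gap) next
      w <- best[j] + a$weight[i]
      td <- bdist[j] + d
      if (w > best[i] ||
          (w == best[i] && (is.na(prev[i]) || td < bdist[i] ||
                            (td == bdist[i] && j < prev[i])))) {
        best[i] <- w
        bdist[i] <- td
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)  # first maximum: smallest index on ties
  idx <- integer()
  i <- end
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  structure(
    list(anchors = a[idx, , drop = FALSE], total_weight = best[end],
         total_distance = bdist[end]),
    class = "sga_chain"
  )
}

#' @export
print.sga_chain <- function(x, ...) {
  cat("<sga_chain> ", nrow(x$anchors), " anchors, total weight ",
      x$total_weight, "\n", sep = "")
  invisible(x)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Anchors of a chain as a tibble
#' @param x an `sga_chain`
#' @param ... unused
#' @export
tidy.sga_chain <- function(x, ...) x$anchors

#' @export
glance.sga_chain <- function(x, ...) {
  tibble(n_anchors = nrow(x$anchors), total_weight = x$total_weight,
         query_covered = sum(x$anchors$span))
}
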