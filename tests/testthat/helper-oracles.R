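# Independent oracles: classical string DP, explicit alignment graph solved
# by an established shortest-path library, and exhaustive enumerations.

# classical linear-gap global alignment cost (minimization)
oracle_nw <- function(a, b, mu, sigma) {
  la <- nchar(a); lb <- nchar(b)
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  prev <- (0:lb) * sigma
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1)
    cur[1] <- i * sigma
    for (j in seq_len(lb)) {
      d <- prev[j] + (if (ach[i] == bch[j] && ach[i] != "N") 0 else mu)
      cur[j + 1] <- min(d, prev[j + 1] + sigma, cur[j] + sigma)
    }
    prev <- cur
  }
  prev[lb + 1]
}

# explicit product alignment graph, solved by igraph (Bellman-Ford)
oracle_fill_cost <- function(g, sub, p1, p2, mu, sigma) {
  n <- nchar(sub)
  subch <- if (n > 0) strsplit(sub, "")[[1]] else character()
  vid <- function(e, o, q) paste(e, o, q, sep = "_")
  rows <- list()
  for (e in seq_len(nrow(g$edges))) {
    len <- g$edges$length[e]
    lab <- strsplit(g$edges$label[e], "")[[1]]
    grid <- expand.grid(o = 0:len, q = 0:n)
    d <- grid[grid$o < len, ]
    rows[[length(rows) + 1]] <- data.frame(
      from = vid(e, d$o, d$q), to = vid(e, d$o + 1, d$q), w = sigma)
    if (n > 0) {
      i <- grid[grid$q < n, ]
      rows[[length(rows) + 1]] <- data.frame(
        from = vid(e, i$o, i$q), to = vid(e, i$o, i$q + 1), w = sigma)
      dd <- grid[grid$o < len & grid$q < n, ]
      if (nrow(dd)) {
        match <- lab[dd$o + 1] == subch[dd$q + 1] & lab[dd$o + 1] != "N"
        rows[[length(rows) + 1]] <- data.frame(
          from = vid(e, dd$o, dd$q), to = vid(e, dd$o + 1, dd$q + 1),
          w = ifelse(match, 0, mu))
      }
    }
  }
  if (nrow(g$links)) {
    for (l in seq_len(nrow(g$links))) {
      fe <- g$links$from[l]; te <- g$links$to[l]; ov <- g$links$overlap[l]
      rows[[length(rows) + 1]] <- data.frame(
        from = vid(fe, g$edges$length[fe], 0:n), to = vid(te, ov, 0:n), w = 0)
    }
  }
  ed <- do.call(rbind, rows)
  gr <- igraph::graph_from_data_frame(ed[, c("from", "to")])
  src <- vid(p1$edge, p1$offset, 0)
  dst <- vid(p2$edge, p2$offset, n)
  if (!(src %in% igraph::V(gr)$name) || !(dst %in% igraph::V(gr)$name)) {
    return(Inf)
  }
  igraph::distances(gr, v = src, to = dst, mode = "out", weights = ed$w,
                    algorithm = "bellman-ford")[1, 1]
}

# bp distance oracle on the explicit position graph
oracle_graph_distance <- function(g, a, b) {
  vid <- function(e, o) paste(e, o, sep = "_")
  rows <- list()
  for (e in seq_len(nrow(g$edges))) {
    len <- g$edges$length[e]
    if (len > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        from = vid(e, 0:(len - 1)), to = vid(e, 1:len), w = 1)
    }
  }
  if (nrow(g$links)) {
    rows[[length(rows) + 1]] <- data.frame(
      from = vid(g$links$from, g$edges$length[g$links$from]),
      to = vid(g$links$to, g$links$overlap), w = 0)
  }
  ed <- do.call(rbind, rows)
  gr <- igraph::graph_from_data_frame(ed[, c("from", "to")])
  src <- vid(a$edge, a$offset); dst <- vid(b$edge, b$offset)
  igraph::distances(gr, v = src, to = dst, mode = "out", weights = ed$w,
                    algorithm = "bellman-ford")[1, 1]
}

# exhaustive heaviest-chain search over all increasing anchor subsequences
brute_chain_weight <- function(g, anchors, alpha = 1.3) {
  a <- dplyr::arrange(anchors, qs, edge, es)
  n <- nrow(a)
  if (n == 0) return(0)
  comp <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) comp[i, j] <- compatible_anchors(g, a[i, ], a[j, ], alpha)
    }
  }
  best <- 0
  dfs <- function(last, w) {
    best <<- max(best, w)
    nxt <- if (is.null(last)) seq_len(n) else which(comp[last, ])
    for (k in nxt) {
      if (is.null(last) || k > last) dfs(k, w + a$weight[k])
    }
  }
  # anchors sorted by qs: any valid chain is an increasing index sequence
  dfs(NULL, 0)
  best
}

# replay a cigar between a query fragment and a path label, recomputing the
# cost and match counts from scratch
replay_cigar <- function(sub, lab, cigar, mu, sigma) {
  if (!nzchar(cigar)) {
    stopifnot(nchar(sub) == 0, nchar(lab) == 0)
    return(list(cost = 0, n_match = 0L))
  }
  parts <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  len <- as.integer(sub("[A-Z]$", "", parts))
  op <- sub("^[0-9]+", "", parts)
  qi <- 0L; li <- 0L; cost <- 0; nm <- 0L
  subch <- strsplit(sub, "")[[1]]; labch <- strsplit(lab, "")[[1]]
  for (r in seq_along(op)) {
    if (op[r] == "M") {
      for (x in seq_len(len[r])) {
        qi <- qi + 1L; li <- li + 1L
        if (subch[qi] == labch[li] && subch[qi] != "N") nm <- nm + 1L
        else cost <- cost + mu
      }
    } else if (op[r] == "I") {
      qi <- qi + len[r]; cost <- cost + sigma * len[r]
    } else if (op[r] == "D") {
      li <- li + len[r]; cost <- cost + sigma * len[r]
    } else stop("unknown op ", op[r])
  }
  stopifnot(qi == nchar(sub), li == nchar(lab))
  list(cost = cost, n_match = nm)
}

# protein global alignment score oracle (maximization)
oracle_protein_score <- function(q, s, matrix, gap) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = matrix, gapOpening = 0, gapExtension = gap,
    type = "global"))
}
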