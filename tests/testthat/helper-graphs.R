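# toy and random graphs used across the suite

# two parallel branches between the ends of a stem: stem -> {brA | brB} -> tail
bubble_graph <- function(brA = "AAA", brB = "AGA", stem = "TTTTT",
                         tail = "CCCCC") {
  assembly_graph(
    c(stem = stem, brA = brA, brB = brB, tail = tail),
    tibble::tibble(
      from = c("stem", "stem", "brA", "brB"),
      from_orient = "+",
      to = c("brA", "brB", "tail", "tail"),
      to_orient = "+",
      overlap = 0L
    )
  )
}

random_graph <- function(n_edges = 5, max_len = 15, seed = 1,
                         n_links = NULL) {
  set.seed(seed)
  n <- n_edges
  segs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(3:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  names(segs) <- paste0("s", seq_len(n))
  if (is.null(n_links)) n_links <- max(1L, round(1.5 * n))
  links <- tibble::tibble(
    from = paste0("s", sample(n, n_links, replace = TRUE)),
    from_orient = sample(c("+", "-"), n_links, replace = TRUE),
    to = paste0("s", sample(n, n_links, replace = TRUE)),
    to_orient = sample(c("+", "-"), n_links, replace = TRUE),
    overlap = 0L
  )
  assembly_graph(segs, unique(links))
}

random_pos <- function(g) {
  e <- sample(nrow(g$edges), 1)
  graph_pos(e, sample(0:g$edges$length[e], 1))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# nucleotide sequence of n sense (non-stop) codons
random_stop_free_nt <- function(n_codons) {
  b <- c("A", "C", "G", "T")
  codons <- sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
  sense <- codons[translate_nt(codons) != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

edge_id <- function(g, name) match(name, g$edges$name)

make_anchors <- function(g, edge, qs, qe, es, ee) {
  tibble::tibble(
    edge = as.integer(edge), edge_name = g$edges$name[as.integer(edge)],
    qs = as.integer(qs), qe = as.integer(qe),
    es = as.integer(es), ee = as.integer(ee),
    span = as.integer(qe - qs), weight = as.numeric(qe - qs)
  )
}
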