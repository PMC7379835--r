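test_that("fill_between solves the spelled-out toy cases", {
  g <- assembly_graph(c(e = "ACGTACGT"))
  # empty fragment, coincident endpoints
  r0 <- fill_between(g, "", graph_pos("e+", 2), graph_pos("e+", 2))
  expect_true(r0$found)
  expect_equal(r0$cost, 0)
  # exact interior slice
  r1 <- fill_between(g, "GTAC", graph_pos("e+", 2), graph_pos("e+", 6))
  expect_equal(r1$cost, 0)
  expect_equal(r1$identity, 1)
  # one substitution
  r2 <- fill_between(g, "GTTC", graph_pos("e+", 2), graph_pos("e+", 6))
  expect_equal(r2$cost, 1)
  # bubble: the matching branch is chosen
  gb <- bubble_graph(brA = "AAA", brB = "AGA")
  r3 <- fill_between(gb, "AGA", graph_pos("stem+", 5),
                     graph_pos("tail+", 0))
  expect_equal(r3$cost, 0)
  expect_true("brB+" %in% r3$edge_names)
  expect_false("brA+" %in% r3$edge_names)
  # unreachable target reports a bounded-search failure
  g2 <- assembly_graph(c(a = "ACGTACGT", b = "GGGGCCCC"))
  rf <- fill_between(g2, "ACGT", graph_pos("a+", 0), graph_pos("b+", 4))
  expect_false(rf$found)
})

test_that("single-edge costs equal the classical linear-gap DP", {
  for (seed in 1:40) {
    set.seed(seed)
    lab <- random_dna_str(sample(5:25, 1))
    sub <- random_dna_str(sample(0:25, 1))
    mu <- sample(0:3, 1); sigma <- sample(0:3, 1)
    g <- assembly_graph(c(e = lab))
    r <- fill_between(g, sub, graph_pos("e+", 0),
                      graph_pos("e+", nchar(lab)),
                      scoring_scheme(mu, sigma), engine = "dijkstra")
    expect_equal(r$cost, oracle_nw(sub, lab, mu, sigma))
  }
})

test_that("returned paths replay their cigar to the reported cost", {
  for (seed in 1:15) {
    set.seed(seed)
    g <- random_graph(n_edges = 4, max_len = 12, seed = 300 + seed)
    mu <- sample(1:3, 1); sigma <- sample(1:3, 1)
    sub <- random_dna_str(sample(1:20, 1))
    p1 <- random_pos(g)
    r <- extend_terminal(g, sub, p1, "right", scoring_scheme(mu, sigma),
                         engine = "dijkstra")
    if (!r$found) next
    lab <- label_of_path(g, r$edges, r$start_offset, r$end_offset)
    rep <- replay_cigar(sub, lab, r$cigar, mu, sigma)
    expect_equal(rep$cost, r$cost)
    expect_equal(rep$n_match, r$n_match)
    expect_gte(r$cost, 0)
  }
})

test_that("cost is zero exactly when the fragment is spelled by a path", {
  set.seed(21)
  g <- random_graph(n_edges = 5, max_len = 12, seed = 77)
  # a fragment read off an actual path has cost 0
  e1 <- which(g$edges$length >= 4)[1]
  sub <- substr(g$edges$label[e1], 2, g$edges$length[e1] - 1)
  r <- fill_between(g, sub, graph_pos(e1, 1),
                    graph_pos(e1, g$edges$length[e1] - 1))
  expect_equal(r$cost, 0)
  # and a fragment that differs from every connecting label has cost > 0
  lab <- g$edges$label[e1]
  bad <- chartr("ACGT", "CAGT", substr(lab, 2, nchar(lab) - 1))
  if (bad != substr(lab, 2, nchar(lab) - 1)) {
    r2 <- fill_between(g, bad, graph_pos(e1, 1),
                       graph_pos(e1, g$edges$length[e1] - 1))
    expect_gt(r2$cost, 0)
  }
})

test_that("left extension mirrors right extension through the rc strand", {
  set.seed(31)
  lab <- random_dna_str(60)
  g <- assembly_graph(c(e = lab))
  # extending left by the exact prefix is free and lands at offset 0
  r <- extend_terminal(g, substr(lab, 1, 20), graph_pos("e+", 20), "left")
  expect_equal(r$cost, 0)
  expect_equal(r$start_offset, 0)
  expect_equal(r$edge_names, "e+")
  # two substitutions cost 2 * mu
  frag <- substr(lab, 1, 20)
  substr(frag, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(frag, 5, 5))[1]
  substr(frag, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                  substr(frag, 12, 12))[1]
  r2 <- extend_terminal(g, frag, graph_pos("e+", 20), "left",
                        scoring_scheme(1, 10))
  expect_equal(r2$cost, 2)
  # empty fragment: empty result, cost 0
  r3 <- extend_terminal(g, "", graph_pos("e+", 20), "left")
  expect_equal(r3$cost, 0)
})

test_that("align_nt_query recovers exact multi-edge paths end to end", {
  set.seed(41)
  gen <- random_dna_str(20000)
  g <- build_compacted_dbg(c(gen, substr(gen, 3000, 8000)), 21)
  q <- substr(gen, 2000, 9000)
  aln <- align_nt_query(g, q, "q")
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$identity, 1)
  expect_true(aln$mapped)
  expect_equal(aln$qstart, 0L)
  expect_equal(aln$qend, nchar(q))
  # the reported path spells the query
  tp <- trace_path(g, q)
  expect_equal(aln$path, paste(tp$edge_names, collapse = ","))

  # a random unrelated query stays unaligned
  set.seed(42)
  rnd <- random_dna_str(500)
  expect_equal(nrow(align_nt_query(g, rnd, "rnd")), 0L)
})

test_that("mapped and identity metrics follow their definitions", {
  aln <- tibble::tibble(query = "q", qstart = 0L, qend = 80L, qlen = 100L,
                        n_match = 85L, n_mismatch = 5L, n_ins = 0L,
                        n_del = 0L, identity = 85 / 90)
  expect_true(is_mapped(aln))
  aln$qend <- 79L
  expect_false(is_mapped(aln))
  # cigar 90M with 5 mismatches: identity 85/90
  expect_equal(alignment_identity(aln), 85 / 90)
})
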