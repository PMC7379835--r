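test_that("GFA round trips: segments, both orientations, overlap handling", {
  f <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0", "S\tx\tACGT"), f)
  g <- load_gfa(f)
  expect_equal(nrow(g$edges), 2L)
  # ACGT is its own reverse complement
  expect_equal(g$edges$label, c("ACGT", "ACGT"))

  writeLines(c("S\ta\tAAAC", "S\tb\tACGG", "L\ta\t+\tb\t+\t2M"), f)
  g2 <- load_gfa(f)
  expect_equal(label_of_path(g2, c("a+", "b+"), 0, 4), "AAACGG")
  # the mirrored rc link must exist too
  expect_equal(label_of_path(g2, c("b-", "a-"), 0, 4), revcomp("AAACGG"))

  writeLines(character(), f)
  g3 <- load_gfa(f)
  expect_equal(nrow(g3$edges), 0L)

  writeLines(c("S\ta"), f)
  expect_error(load_gfa(f), "line 1")
  writeLines(c("S\ta\tAAAC", "S\tb\tACGG", "L\ta\t+\tb\t+\t4M"), f)
  expect_error(load_gfa(f), "overlap")

  # '*' overlap treated as 0
  writeLines(c("S\ta\tAAAC", "S\tb\tACGG", "L\ta\t+\tb\t+\t*"), f)
  expect_equal(label_of_path(load_gfa(f), c("a+", "b+"), 0, 4), "AAACACGG")

  # write -> read round trip
  f2 <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g2, f2)
  g2b <- load_gfa(f2)
  expect_equal(g2b$edges$label, g2$edges$label)
  expect_equal(nrow(g2b$links), nrow(g2$links))
})

test_that("label_of_path follows offset conventions and trims overlaps", {
  g <- assembly_graph(c(e = "ACGTA"))
  expect_equal(label_of_path(g, "e+", 1, 3), "CG")
  expect_equal(label_of_path(g, "e+", 2, 2), "")
  expect_error(label_of_path(g, "e+", 4, 2), "inconsistent")
  g2 <- assembly_graph(
    c(a = "AAAC", b = "ACGG"),
    tibble::tibble(from = "a", from_orient = "+", to = "b", to_orient = "+",
                   overlap = 2L))
  expect_equal(label_of_path(g2, c("a+", "b+"), 0, 4), "AAACGG")
  expect_error(label_of_path(g2, c("b+", "a+"), 0, 4), "not linked")
})

test_that("reverse-complement path spells the reverse complement label", {
  for (seed in 1:10) {
    g <- random_graph(n_edges = 4, seed = seed)
    # pick a random 1-3 edge walk along existing links
    e1 <- sample(nrow(g$edges), 1)
    path <- e1
    for (step in 1:2) {
      nxt <- g$links$to[g$links$from == path[length(path)]]
      if (length(nxt)) path <- c(path, nxt[sample(length(nxt), 1)])
    }
    lens <- g$edges$length[path]
    so <- sample(0:lens[1], 1)
    eo <- sample(0:lens[length(path)], 1)
    if (length(path) == 1 && eo < so) { tmp <- so; so <- eo; eo <- tmp }
    lab <- label_of_path(g, path, so, eo)
    rc_path <- rev(g$edges$rc[path])
    lab_rc <- label_of_path(g, rc_path,
                            lens[length(path)] - eo, lens[1] - so)
    expect_equal(lab_rc, revcomp(lab))
    # agreement with an independent reverse-complement implementation
    expect_equal(revcomp(lab),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(lab))))
  }
})

test_that("min_graph_distance: same edge, caps, bubbles, oracle, triangle", {
  g <- assembly_graph(c(e = "ACGTACGTAC"))
  expect_equal(min_graph_distance(g, graph_pos("e+", 2), graph_pos("e+", 7)),
               5)
  expect_identical(
    min_graph_distance(g, graph_pos("e+", 7), graph_pos("e+", 2), cap = 1000),
    Inf)

  # bubble with branch labels of lengths 3 and 5: distance across = 3
  gb <- assembly_graph(
    c(stem = "TT", brA = "AAA", brB = "CCCCC", tail = "GG"),
    tibble::tibble(from = c("stem", "stem", "brA", "brB"),
                   from_orient = "+",
                   to = c("brA", "brB", "tail", "tail"),
                   to_orient = "+", overlap = 0L))
  expect_equal(
    min_graph_distance(g = gb, graph_pos("stem+", 2), graph_pos("tail+", 0),
                       cap = 100),
    3)

  # equality with explicit-graph shortest paths, and the triangle inequality
  for (seed in 1:8) {
    gr <- random_graph(n_edges = 5, max_len = 8, seed = 100 + seed)
    set.seed(seed)
    pts <- replicate(3, random_pos(gr), simplify = FALSE)
    d <- function(x, y) min_graph_distance(gr, x, y, cap = 1e6)
    dab <- d(pts[[1]], pts[[2]]); dbc <- d(pts[[2]], pts[[3]])
    dac <- d(pts[[1]], pts[[3]])
    expect_equal(dab, oracle_graph_distance(gr, pts[[1]], pts[[2]]))
    if (is.finite(dab) && is.finite(dbc) && is.finite(dac)) {
      expect_lte(dac, dab + dbc)
    }
  }
})

test_that("extract_neighborhood bounds the reachable subgraph", {
  g <- assembly_graph(
    c(a = strrep("A", 50) %>% paste0(strrep("C", 50)),
      b = strrep("G", 100), c = strrep("T", 100)),
    tibble::tibble(from = c("a", "b"), from_orient = "+",
                   to = c("b", "c"), to_orient = "+", overlap = 0L))
  seed <- graph_pos("a+", 0)
  nb0 <- extract_neighborhood(g, list(seed), 0)
  expect_setequal(unique(nb0$edges$segment), "a")
  nb150 <- extract_neighborhood(g, list(seed), 150)
  expect_setequal(unique(nb150$edges$segment), c("a", "b"))
  nball <- extract_neighborhood(g, list(seed), sum(g$edges$length))
  expect_setequal(unique(nball$edges$segment), c("a", "b", "c"))
})
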