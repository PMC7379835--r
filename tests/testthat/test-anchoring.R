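test_that("find_anchors recovers exact and near-exact matches", {
  set.seed(5)
  lab <- random_dna_str(300)
  g <- assembly_graph(c(e = lab))

  # query equal to the edge label: one anchor covering the full edge
  a <- find_anchors(g, lab, k_seed = 14, min_span = 14)
  full <- a[a$edge_name == "e+", ]
  expect_true(any(full$qs == 0 & full$qe == 300 & full$es == 0 &
                    full$ee == 300))
  expect_equal(full$span[full$qs == 0 & full$qe == 300], 300)

  # no shared 14-mer: empty result
  q2 <- strrep("AC", 50)
  expect_equal(nrow(find_anchors(assembly_graph(c(e = strrep("G", 120))), q2)),
               0L)

  # one substitution in the middle of a 100 bp label: anchors jointly
  # cover at least 86 bp of the query
  lab1 <- random_dna_str(100)
  q <- lab1
  mid <- substr(q, 50, 50)
  substr(q, 50, 50) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  g1 <- assembly_graph(c(e = lab1))
  a1 <- find_anchors(g1, q, k_seed = 14, min_span = 14, max_gap = 0)
  a1 <- a1[a1$edge_name == "e+", ]
  cov <- sum(a1$qe - a1$qs)
  expect_gte(cov, 86)

  # determinism and sort order
  a2 <- find_anchors(g, lab, k_seed = 14, min_span = 14)
  expect_identical(a, a2)
  expect_true(!is.unsorted(a$qs))
})

test_that("filter rules fire in order with the printed defaults", {
  g <- assembly_graph(c(big = strrep("A", 10000), sm = strrep("C", 1000)))

  # rule 3: span 150 < t = 200 discarded
  a <- make_anchors(g, 3, qs = 0, qe = 150, es = 0, ee = 150)
  expect_equal(nrow(filter_anchors(a, 1000, g)), 0L)

  # rule 1 worked inequality: |e| = 10000, edge range [4000,4300),
  # query length 1000, query range [400,700):
  # 300 + 400 + 300 = 1000 > 3*300 = 900, span 300 < T = 500 -> discarded
  a1 <- make_anchors(g, 1, qs = 400, qe = 700, es = 4000, ee = 4300)
  expect_equal(nrow(filter_anchors(a1, 1000, g)), 0L)
  # same anchor with span >= T survives rule 1 (and t)
  a1b <- make_anchors(g, 1, qs = 100, qe = 700, es = 4000, ee = 4600)
  expect_equal(nrow(filter_anchors(a1b, 1000, g)), 1L)

  # rule 2: of two anchors with identical query ranges exactly one survives
  a2 <- make_anchors(g, c(1, 3), qs = c(0, 0), qe = c(300, 300),
                     es = c(0, 0), ee = c(300, 300))
  f2 <- filter_anchors(a2, 320, g)
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$edge, 1L)  # tie towards the smallest edge id

  # a small anchor mostly covered by a bigger one is dropped, keeper stays
  a3 <- make_anchors(g, c(1, 3), qs = c(0, 20), qe = c(300, 260),
                     es = c(0, 0), ee = c(300, 240))
  f3 <- filter_anchors(a3, 320, g)
  expect_equal(f3$edge, 1L)
})

test_that("filtering is idempotent and survivors span at least t", {
  for (seed in 1:6) {
    set.seed(seed)
    g <- assembly_graph(c(e1 = random_dna_str(2000), e2 = random_dna_str(800)))
    n <- 12
    qs <- sample(0:700, n)
    spans <- sample(c(50, 150, 250, 400, 600), n, replace = TRUE)
    edge <- sample(c(1L, 3L), n, replace = TRUE)
    elen <- g$edges$length[edge]
    es <- pmin(sample(0:500, n), elen - spans - 1)
    es <- pmax(es, 0)
    keepable <- es + spans <= elen & qs + spans <= 1000
    a <- make_anchors(g, edge[keepable], qs[keepable],
                      qs[keepable] + spans[keepable], es[keepable],
                      es[keepable] + spans[keepable])
    f1 <- filter_anchors(a, 1000, g)
    expect_identical(filter_anchors(f1, 1000, g), f1)
    expect_true(all(f1$span >= 200))
  }
})

test_that("a query equal to one long edge yields a single surviving anchor", {
  set.seed(11)
  lab <- random_dna_str(400)
  g <- assembly_graph(c(e = lab))
  a <- find_anchors(g, lab, k_seed = 14, min_span = 14)
  f <- filter_anchors(a, 400, g)
  f <- f[f$edge_name == "e+", ]
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$qs, f$qe), c(0L, 400L))
})

test_that("PAF-imported anchors flow through filtering like internal ones", {
  set.seed(13)
  lab <- random_dna_str(400)
  g <- assembly_graph(c(e = lab))
  internal <- find_anchors(g, lab, k_seed = 14, min_span = 14)
  internal <- internal[internal$edge_name == "e+", ][1, ]
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("q1", 400, internal$qs, internal$qe, "+", "e", 400,
                   internal$es, internal$ee, 400, 400, 60, sep = "\t"), paf)
  imported <- read_paf_anchors(paf, g, query = "q1")
  expect_equal(imported$edge, internal$edge)
  expect_identical(
    filter_anchors(imported, 400, g)[, c("edge", "qs", "qe", "es", "ee")],
    filter_anchors(internal, 400, g)[, c("edge", "qs", "qe", "es", "ee")])

  # reverse-strand PAF records map onto the '-' edge with mirrored coords
  writeLines(paste("q1", 400, 10, 60, "-", "e", 400, 100, 150, 50, 50, 60,
                   sep = "\t"), paf)
  rcrec <- read_paf_anchors(paf, g)
  expect_equal(rcrec$edge_name, "e-")
  expect_equal(c(rcrec$es, rcrec$ee), c(250L, 300L))
})
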