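test_that("translation and canonical codons follow the standard code", {
  expect_equal(translate_nt("ATG"), "M")
  expect_equal(translate_nt("ATGGCTTAA"), "MA*")
  expect_error(translate_nt("ATGG"), "divisible")
  expect_equal(canonical_codon("M"), "ATG")
  expect_equal(canonical_codon("K"), "AAA")   # AAA < AAG
  expect_equal(canonical_codon("*"), "TAA")
  expect_equal(canonical_nt("MK"), "ATGAAA")
  expect_error(canonical_codon("J"), "unknown")
  # canonical encoding round-trips through translation
  set.seed(2)
  p <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G"), 30,
                    replace = TRUE), collapse = "")
  expect_equal(translate_nt(canonical_nt(p)), p)
})

test_that("protein anchors respect frames and minimum length", {
  set.seed(6)
  nt <- random_stop_free_nt(60)        # 180 bp ORF body
  q <- translate_nt(nt)
  lab <- paste0("CC", nt, random_dna_str(30))  # frame 2 on this edge
  g <- assembly_graph(c(e = lab))
  a <- find_aa_anchors(g, q, min_len = 15)
  hit <- a[a$edge_name == "e+" & a$frame == 2, ]
  expect_gte(nrow(hit), 1L)
  full <- hit[hit$qs == 0 & hit$qe == 60, ]
  expect_equal(nrow(full), 1L)
  expect_equal(c(full$es, full$ee), c(2L, 182L))
  # nucleotide coordinates stay frame-consistent
  expect_true(all((a$es - a$frame) %% 3 == 0))
  # a query with no 5-codon match anywhere yields nothing
  expect_equal(nrow(find_aa_anchors(g, strrep("W", 40), min_len = 15)), 0L)
})

test_that("perfect-match extension scores the sum of diagonal entries", {
  sc <- aa_scoring_scheme()
  g <- assembly_graph(c(e = "ATGGCT"))
  r <- extend_aa(g, "MA", graph_pos("e+", 0), "right", sc)
  expect_true(r$found)
  M <- sc$matrix
  expect_equal(r$score, M["M", "M"] + M["A", "A"])
  # shift law: SG' weight minus SG weight is exactly |query| * C
  expect_equal(r$weight - r$sg_weight, 2 * sc$shift)
  expect_equal(r$nt_consumed, 6L)
})

test_that("stop codons are excluded from AA-paths", {
  g <- assembly_graph(
    c(stem = "ATG", brA = "TAA", brB = "GCT"),
    tibble::tibble(from = c("stem", "stem"), from_orient = "+",
                   to = c("brA", "brB"), to_orient = "+", overlap = 0L))
  sc <- aa_scoring_scheme()
  r <- extend_aa(g, "MA", graph_pos("stem+", 0), "right", sc)
  expect_true(r$found)
  expect_true("brB+" %in% r$edge_names)
  expect_false("brA+" %in% r$edge_names)
  lab <- label_of_path(g, r$edges, 0, r$end_offset)
  expect_false(grepl("\\*", translate_nt(lab)))
})

test_that("the optimum is invariant to the shift constant C", {
  sc0 <- aa_scoring_scheme()
  mx <- max(sc0$matrix)
  for (seed in 1:12) {
    set.seed(seed)
    nt <- random_stop_free_nt(sample(8:20, 1))
    g <- assembly_graph(c(e = nt))
    q <- translate_nt(nt)
    q <- mutate_protein(q, 0.2, seed = seed)
    res <- lapply(c(mx + 1, mx + 10, 10 * mx), function(C) {
      extend_aa(g, q, graph_pos("e+", 0), "right",
                aa_scoring_scheme(shift = C))
    })
    ws <- vapply(res, `[[`, numeric(1), "sg_weight")
    expect_equal(ws[2], ws[1])
    expect_equal(ws[3], ws[1])
    expect_equal(res[[1]]$edges, res[[2]]$edges)
    # shifted weights differ by |query| * (C2 - C1) exactly
    expect_equal(res[[2]]$weight - res[[1]]$weight, nchar(q) * 9)
  }
})

test_that("single-path protein scores equal the classical global aligner", {
  sc <- aa_scoring_scheme()
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:25, 1)
    nt <- random_stop_free_nt(n)
    g <- assembly_graph(c(e = nt))
    q <- mutate_protein(translate_nt(nt), 0.25, seed = 500 + seed)
    r <- extend_aa(g, q, graph_pos("e+", 0), "right", sc,
                   to = graph_pos("e+", nchar(nt)))
    expect_true(r$found)
    expect_equal(r$score,
                 oracle_protein_score(q, translate_nt(nt), sc$matrix, sc$gap))
    # frame bookkeeping: consumed nucleotides = 3 * (residues + deletions)
    expect_equal(r$nt_consumed, 3L * (r$n_res + r$n_del_codons))
    expect_equal(nchar(nt), r$nt_consumed)  # target forces the full label
  }
})

test_that("align_protein recovers genes across edges and filters by coverage", {
  set.seed(71)
  gen <- random_dna_str(12000)
  orf <- paste0("ATG", random_stop_free_nt(120), "TAA")
  substr(gen, 4001, 4000 + nchar(orf)) <- orf
  # duplicate a window overlapping the ORF so its path crosses branch points
  g <- build_compacted_dbg(c(gen, substr(gen, 3500, 4300)), 21)
  q <- translate_nt(substr(orf, 1, nchar(orf) - 3))
  res <- align_protein(g, q, "orf")
  expect_gte(nrow(res), 1L)
  expect_equal(res$coverage[1], 1)
  expect_equal(res$identity[1], 1)
  expect_equal(res$translated[1], q)
  tp <- trace_path(g, substr(orf, 1, nchar(orf) - 3))
  expect_equal(res$path[1], paste(tp$edge_names, collapse = ","))
  # stop-codon law on every output
  expect_false(any(grepl("\\*", res$translated)))

  # mutated query still recovers the planted path
  qm <- mutate_protein(q, 0.1, seed = 7)
  resm <- align_protein(g, qm, "orfm")
  expect_gte(nrow(resm), 1L)
  expect_equal(resm$path[1], paste(tp$edge_names, collapse = ","))
  expect_gte(resm$identity[1], 0.85)

  # a 70% fragment of the query cannot reach 0.8 coverage of the full query
  q70 <- substr(q, 1, floor(0.7 * nchar(q)))
  res70 <- align_protein(g, paste0(q70, strrep("W", nchar(q) - nchar(q70))),
                         "frag")
  if (nrow(res70)) expect_gte(res70$coverage[1], 0.8)
})

test_that("bundled matrices parse and satisfy scheme invariants", {
  M <- blosum90()
  expect_equal(M["M", "M"], 7)
  expect_equal(M, t(M))
  expect_equal(dim(M), c(24L, 24L))
  M62 <- blosum62()
  expect_equal(M62["W", "W"], 11)
  sc <- aa_scoring_scheme()
  expect_gt(sc$shift, max(sc$matrix))  # all shifted weights non-negative
  expect_error(aa_scoring_scheme(shift = 0), "exceed")
})
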