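test_that("genome simulation is seed-reproducible and plants valid ORFs", {
  cfg <- simulation_config(genome_length = 20000L, n_orfs = 4L,
                           n_reads = 5L, seed = 3L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_equal(nchar(s1$genome), 20000L)
  for (i in seq_len(nrow(s1$orfs))) {
    nt <- substr(s1$genome, s1$orfs$start[i] + 1, s1$orfs$end[i])
    expect_equal(substr(nt, 1, 3), "ATG")
    tr <- translate_nt(nt)
    # no internal stop; terminal stop present
    expect_false(grepl("\\*", substr(tr, 1, nchar(tr) - 1)))
    expect_equal(substr(tr, nchar(tr), nchar(tr)), "*")
    expect_identical(translate_nt(substr(nt, 1, nchar(nt) - 3)),
                     s1$orfs$protein[i])
  }
  expect_error(
    simulate_genome(simulation_config(genome_length = 500L,
                                      repeat_length = 600L)),
    "longer than the genome")
})

test_that("compacted DBG construction matches k-mer structure", {
  set.seed(12)
  gen <- random_dna_str(5000)
  g <- build_compacted_dbg(gen, 21)
  # repeat-free genome: a single unitig pair
  expect_equal(nrow(g$edges), 2L)
  expect_true(gen %in% g$edges$label)

  # an exact repeat >= k forces branching (more than 2 unitigs)
  rep500 <- substr(gen, 1001, 1500)
  gen2 <- paste0(gen, "ACGTT", rep500, "GTCAA")
  g2 <- build_compacted_dbg(gen2, 21)
  expect_gt(nrow(g2$edges), 2L)

  # the ground-truth path of the full genome spells the genome
  tp <- trace_path(g2, gen2)
  expect_equal(label_of_path(g2, tp$edges, tp$start_offset, tp$end_offset),
               gen2)

  # planted 100%-identity repeats produce a branching node
  cfg <- simulation_config(genome_length = 20000L, n_repeat_units = 1L,
                           repeat_copies = 2L, repeat_identity = 1,
                           n_orfs = 0L, seed = 5L)
  s <- simulate_genome(cfg)
  gg <- build_compacted_dbg(s$genome, cfg$k)
  expect_gt(nrow(gg$edges), 2L)
  tpg <- trace_path(gg, s$genome)
  expect_equal(label_of_path(gg, tpg$edges, tpg$start_offset, tpg$end_offset),
               s$genome)
})

test_that("read simulation honors its error process", {
  cfg0 <- simulation_config(genome_length = 20000L, n_reads = 10L,
                            error_mismatch = 0, error_ins = 0, error_del = 0,
                            n_orfs = 0L, seed = 9L)
  s <- simulate_genome(cfg0)
  reads <- simulate_reads(s$genome, cfg0)
  for (i in seq_len(nrow(reads))) {
    tmpl <- substr(s$genome, reads$start[i] + 1, reads$end[i])
    if (reads$strand[i] == "-") tmpl <- revcomp(tmpl)
    expect_identical(reads$seq[i], tmpl)
  }

  # mismatch-only process: observed rate within 3 sd of binomial expectation
  cfgm <- simulation_config(genome_length = 60000L, n_reads = 15L,
                            read_length = c(3000L, 4000L),
                            error_mismatch = 0.1, error_ins = 0,
                            error_del = 0, n_orfs = 0L, seed = 11L)
  sm <- simulate_genome(cfgm)
  rm_ <- simulate_reads(sm$genome, cfgm)
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(rm_))) {
    tmpl <- substr(sm$genome, rm_$start[i] + 1, rm_$end[i])
    if (rm_$strand[i] == "-") tmpl <- revcomp(tmpl)
    a <- strsplit(rm_$seq[i], "")[[1]]
    b <- strsplit(tmpl, "")[[1]]
    mism <- mism + sum(a != b)
    tot <- tot + length(b)
  }
  p <- mism / tot
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / tot))
})

test_that("protein mutation is controlled and length-preserving", {
  p <- strrep("MARNDCQEGH", 10)
  expect_identical(mutate_protein(p, 0, seed = 1), p)
  pm <- mutate_protein(p, 0.2, seed = 1)
  expect_equal(nchar(pm), nchar(p))
  d <- mean(strsplit(p, "")[[1]] != strsplit(pm, "")[[1]])
  expect_lt(abs(d - 0.2), 0.15)
  expect_identical(mutate_protein(p, 0.2, seed = 1), pm)
})

test_that("error-free reads round-trip through the aligner exactly", {
  cfg <- simulation_config(genome_length = 30000L, n_reads = 12L,
                           read_length = c(1000L, 2000L),
                           error_mismatch = 0, error_ins = 0, error_del = 0,
                           seed = 17L)
  s <- simulate_genome(cfg)
  g <- build_compacted_dbg(s$genome, cfg$k)
  reads <- simulate_reads(s$genome, cfg)
  aln <- align_nt(g, setNames(reads$seq, reads$read))
  expect_equal(nrow(aln), nrow(reads))
  expect_true(all(aln$identity == 1))
  expect_true(all(aln$mapped))
  # recovered labels equal the true substrings
  m <- match(aln$query, reads$read)
  for (i in seq_len(nrow(aln))) {
    tp <- trace_path(g, if (reads$strand[m[i]] == "-") {
      revcomp(substr(s$genome, reads$start[m[i]] + 1, reads$end[m[i]]))
    } else {
      substr(s$genome, reads$start[m[i]] + 1, reads$end[m[i]])
    })
    expect_equal(aln$path[i], paste(tp$edge_names, collapse = ","))
  }
})
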