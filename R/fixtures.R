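BASES <- c("A", "C", "G", "T")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Simulation configuration
#'
#' Study conditions for the built-in simulator: a random genome with planted
#' near-identical repeats (so the de Bruijn graph branches) and planted ORFs;
#' long reads drawn from either strand with a per-base error process; and
#' point-mutated query proteins. A fixed seed makes every output
#' byte-identical across runs.
#'
#' @param genome_length genome size in bp
#' @param k de Bruijn k-mer size (odd, 11-31)
#' @param n_repeat_units number of distinct repeat units
#' @param repeat_copies copies planted per unit
#' @param repeat_length repeat unit length (bp)
#' @param repeat_identity sequence identity between copies of a unit
#' @param n_orfs planted open reading frames
#' @param orf_length ORF length range in codons (start/stop codons added)
#' @param n_reads simulated reads
#' @param read_length read length range (bp)
#' @param error_mismatch,error_ins,error_del per-base error rates
#' @param protein_mutation per-residue substitution rate for query proteins
#' @param seed random seed
#' @export
simulation_config <- function(genome_length = 100000L, k = 21L,
                              n_repeat_units = 2L, repeat_copies = 2L,
                              repeat_length = 500L, repeat_identity = 0.97,
                              n_orfs = 20L, orf_length = c(100L, 300L),
                              n_reads = 200L, read_length = c(2000L, 5000L),
                              error_mismatch = 0.06, error_ins = 0.02,
                              error_del = 0.02, protein_mutation = 0.1,
                              seed = 42L) {
  stopifnot(all(c(error_mismatch, error_ins, error_del, protein_mutation,
                  repeat_identity) >= 0),
            all(c(error_mismatch, error_ins, error_del, protein_mutation,
                  repeat_identity) <= 1),
            error_mismatch + error_ins + error_del <= 1,
            genome_length >= 10 * k)
  structure(mget(names(formals(simulation_config))),
            class = "simulation_config")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

random_orf <- function(n_codons) {
  codons <- names(codon_table())
  sense <- codons[!codon_table() %in% c("*", "M")]
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Simulate a genome with planted repeats and ORFs
#'
#' Features (repeat copies and ORFs) are planted by replacement at
#' non-overlapping, randomly offset positions, so the genome length is
#' exactly `cfg$genome_length`. Planted ORFs have a start codon, no internal
#' stop, and a final stop codon; repeat copies are mutated down to
#' `repeat_identity`.
#'
#' @param cfg a [simulation_config()]
#' @return list with `genome` (string), `orfs` and `repeats` annotation
#'   tibbles carrying true coordinates (0-based half-open)
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  g <- random_dna(cfg$genome_length)

  n_rep <- cfg$n_repeat_units * cfg$repeat_copies
  orf_codons <- if (cfg$n_orfs > 0) {
    sample(seq(cfg$orf_length[1], cfg$orf_length[2]), cfg$n_orfs,
           replace = TRUE)
  } else integer()
  feat_len <- c(rep(cfg$repeat_length, n_rep), 3L * (orf_codons + 1L))
  n_feat <- length(feat_len)
  if (n_feat > 0) {
    if (any(feat_len > cfg$genome_length)) {
      stop("planted feature longer than the genome")
    }
    block <- cfg$genome_length %/% n_feat
    if (any(feat_len > block)) {
      stop("features do not fit: genome too short for the requested ",
           "repeats and ORFs")
    }
    ord <- sample.int(n_feat)
    starts <- integer(n_feat)
    for (j in seq_len(n_feat)) {
      i <- ord[j]
      starts[i] <- (j - 1L) * block +
        sample.int(block - feat_len[i] + 1L, 1) - 1L
    }
  } else {
    starts <- integer()
  }

  repeats <- tibble(unit = integer(), copy = integer(), start = integer(),
                    end = integer())
  units <- replicate(cfg$n_repeat_units, random_dna(cfg$repeat_length))
  idx <- 0L
  for (u in seq_len(cfg$n_repeat_units)) {
    for (cp in seq_len(cfg$repeat_copies)) {
      idx <- idx + 1L
      s <- starts[idx]
      seqv <- if (cp == 1) units[u] else mutate_dna(units[u],
                                                    1 - cfg$repeat_identity)
      substr(g, s + 1L, s + cfg$repeat_length) <- seqv
      repeats <- bind_rows(repeats, tibble(unit = u, copy = cp, start = s,
                                           end = s + cfg$repeat_length))
    }
  }

  orfs <- tibble(name = character(), start = integer(), end = integer(),
                 n_codons = integer(), protein = character())
  for (o in seq_len(cfg$n_orfs)) {
    idx <- idx + 1L
    s <- starts[idx]
    nt <- random_orf(orf_codons[o])
    substr(g, s + 1L, s + nchar(nt)) <- nt
    prot <- cpp_translate(substr(nt, 1, nchar(nt) - 3L))  # sans stop codon
    orfs <- bind_rows(orfs, tibble(
      name = sprintf("orf%02d", o), start = s, end = s + nchar(nt),
      n_codons = orf_codons[o], protein = prot
    ))
  }
  list(genome = g, orfs = orfs, repeats = repeats)
}

#' Compacted de Bruijn graph of one or more sequences
#'
#' Standard node-centric construction over canonical k-mers: unitigs become
#' segments, adjacent segments overlap by k-1 bp, both strands are present.
#' Segment ids are deterministic (lexicographic order of canonical unitig
#' sequences). Every substring of the input maps to a unique path, which
#' [trace_path()] recovers.
#'
#' @param seqs character vector of sequences
#' @param k odd k in 11..31
#' @return an `assembly_graph`
#' @export
build_compacted_dbg <- function(seqs, k) {
  raw <- cpp_build_dbg(toupper(as.character(seqs)), as.integer(k))
  n <- length(raw$segments)
  segs <- setNames(raw$segments, paste0("u", seq_len(n)))
  links <- tibble(
    from = paste0("u", raw$link_from),
    from_orient = raw$link_from_orient,
    to = paste0("u", raw$link_to),
    to_orient = raw$link_to_orient,
    overlap = raw$link_overlap
  )
  assembly_graph(segs, if (nrow(links)) links else NULL, k = as.integer(k))
}

#' Ground-truth path of an exact substring
#'
#' Walks a sequence through the graph using its k-mer index; errors if the
#' sequence is not spelled by any path.
#'
#' @param g an `assembly_graph` built with known `k`
#' @param seq exact sequence present in the graph
#' @export
trace_path <- function(g, seq) {
  if (is.na(g$k)) stop("trace_path needs a graph with known k")
  res <- cpp_trace_path(g$cpp, toupper(seq), g$k)
  list(edges = res$edges, edge_names = g$edges$name[res$edges],
       start_offset = res$start_offset, end_offset = res$end_offset)
}

apply_read_errors <- function(seq, pm, pi, pd) {
  ch <- strsplit(seq, "")[[1]]
  u <- runif(length(ch))
  op <- ifelse(u < pm, "X", ifelse(u < pm + pi, "I", ifelse(u < pm + pi + pd,
                                                            "D", "M")))
  out <- character(length(ch))
  for (i in seq_along(ch)) {
    out[i] <- switch(op[i],
      M = ch[i],
      X = sample(setdiff(BASES, ch[i]), 1),
      I = paste0(ch[i], sample(BASES, 1)),
      D = ""
    )
  }
  paste(out, collapse = "")
}

#' Simulate long error-prone reads
#'
#' Reads are drawn uniformly from either strand with lengths uniform in
#' `cfg$read_length`, then passed through a per-base error process drawing
#' among match / mismatch / insertion / deletion with the configured
#' probabilities. Truth records keep the genomic interval and strand.
#'
#' @param genome genome string
#' @param cfg a [simulation_config()]
#' @return tibble: `read`, `seq`, `strand`, `start`, `end` (0-based
#'   half-open on the forward genome)
#' @export
simulate_reads <- function(genome, cfg) {
  set.seed(cfg$seed + 1L)
  glen <- nchar(genome)
  out <- vector("list", cfg$n_reads)
  for (i in seq_len(cfg$n_reads)) {
    len <- sample(seq(cfg$read_length[1], cfg$read_length[2]), 1)
    len <- min(len, glen)
    start <- sample.int(glen - len + 1L, 1) - 1L
    strand <- sample(c("+", "-"), 1)
    tmpl <- substr0(genome, start, start + len)
    if (strand == "-") tmpl <- revcomp(tmpl)
    seqv <- apply_read_errors(tmpl, cfg$error_mismatch, cfg$error_ins,
                              cfg$error_del)
    out[[i]] <- tibble(read = sprintf("read%04d", i), seq = seqv,
                       strand = strand, start = start, end = start + len)
  }
  bind_rows(out)
}

#' Point-mutate a protein
#'
#' Substitutes each residue with probability `rate` by a different residue
#' drawn uniformly from the 20 standard amino acids (length is preserved).
#'
#' @param p protein string
#' @param rate per-residue substitution rate
#' @param seed random seed
#' @export
mutate_protein <- function(p, rate, seed = 1L) {
  set.seed(seed)
  ch <- strsplit(toupper(p), "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}
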