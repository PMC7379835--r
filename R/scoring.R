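#' Nucleotide scoring scheme (linear gaps)
#'
#' Costs are minimized: matches are free, a mismatch costs `mismatch`
#' (\eqn{\mu}) and every gapped base costs `gap` (\eqn{\sigma}). The defaults
#' \eqn{\mu = \sigma = 1} give edit distance, for which the 0-1 BFS engine
#' applies.
#'
#' @param mismatch mismatch cost \eqn{\mu \ge 0}
#' @param gap per-base gap cost \eqn{\sigma \ge 0}
#' @export
scoring_scheme <- function(mismatch = 1, gap = 1) {
  stopifnot(mismatch >= 0, gap >= 0)
  structure(list(mismatch = mismatch, gap = gap), class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#' @param path matrix file (e.g. the bundled BLOSUM90/BLOSUM62)
#' @return numeric matrix with amino-acid dimnames
#' @export
read_blosum <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- vapply(rows, `[[`, character(1), 1)
  colnames(m) <- header
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix rows and columns disagree in ", path)
  }
  m
}

matrix_cache <- new.env(parent = emptyenv())

#' Bundled substitution matrices
#' @return numeric matrix with amino-acid dimnames
#' @export
blosum90 <- function() {
  if (is.null(matrix_cache$b90)) {
    matrix_cache$b90 <- read_blosum(
      system.file("extdata", "BLOSUM90.txt", package = "gfalign"))
  }
  matrix_cache$b90
}

#' @rdname blosum90
#' @export
blosum62 <- function() {
  if (is.null(matrix_cache$b62)) {
    matrix_cache$b62 <- read_blosum(
      system.file("extdata", "BLOSUM62.txt", package = "gfalign"))
  }
  matrix_cache$b62
}

#' Amino-acid scoring scheme with frame-state semantics
#'
#' Protein alignment maximizes the substitution-matrix score, while the graph
#' search minimizes path weight, so the search uses costs `M' = -M`. Because
#' `M'` has negative entries, every query-consuming edge of the alignment
#' graph is shifted by a constant `C > max(M)`, after which all weights are
#' non-negative and Dijkstra applies; every source-to-sink path weight shifts
#' by exactly `|query| * C`, so the optimum is unchanged.
#'
#' @param matrix substitution matrix (default BLOSUM90) or the name of a
#'   bundled matrix
#' @param gap linear gap cost \eqn{\sigma} per residue/codon (default 5)
#' @param shift the constant `C`; default `max(matrix) + 1`
#' @export
aa_scoring_scheme <- function(matrix = "BLOSUM90", gap = 5, shift = NULL) {
  if (is.character(matrix)) {
    matrix <- switch(matrix,
      BLOSUM90 = blosum90(),
      BLOSUM62 = blosum62(),
      read_blosum(matrix)
    )
  }
  stopifnot(is.matrix(matrix), gap >= 0)
  if (is.null(shift)) shift <- max(matrix) + 1
  if (shift <= max(matrix)) stop("shift C must exceed max(matrix)")
  structure(
    list(matrix = matrix, gap = gap, shift = shift,
         alphabet = paste(rownames(matrix), collapse = "")),
    class = "aa_scoring_scheme"
  )
}

#' Translate nucleotide sequences (standard genetic code)
#'
#' @param x character vector; each length must be divisible by 3. Codons
#'   containing ambiguous bases translate to `X`, stop codons to `*`.
#' @export
translate_nt <- function(x) cpp_translate(toupper(as.character(x)))

codon_table <- function() {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)  # lexicographic, A < C < G < T
  setNames(cpp_translate(codons), codons)
}

canonical_cache <- new.env(parent = emptyenv())

#' Canonical codon of an amino acid
#'
#' The lexicographically minimal codon (A < C < G < T) encoding the residue;
#' the canonical nucleotide representation of a protein is the concatenation
#' of its canonical codons.
#'
#' @param aa character vector of single residues (one-letter code, `*` for
#'   stop)
#' @export
canonical_codon <- function(aa) {
  if (is.null(canonical_cache$map)) {
    tab <- codon_table()
    canonical_cache$map <- tapply(names(tab), tab, min)
  }
  aa <- toupper(as.character(aa))
  bad <- !aa %in% names(canonical_cache$map)
  if (any(bad)) stop("unknown residue: ", aa[bad][1])
  unname(canonical_cache$map[aa])
}

#' @rdname canonical_codon
#' @param protein character vector of protein sequences
#' @export
canonical_nt <- function(protein) {
  vapply(strsplit(toupper(as.character(protein)), ""), function(res) {
    paste(canonical_codon(res), collapse = "")
  }, character(1))
}
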