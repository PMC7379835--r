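#' Read an assembly graph from GFA 1.x
#'
#' Parses `S` (segment) and `L` (link) lines. Link overlaps must be `*`
#' (treated as 0) or a single-operation match CIGAR `"<n>M"`. Other line
#' types are ignored with a warning (headers silently).
#'
#' @param path GFA file
#' @param k optional de Bruijn k; when missing it is guessed as the modal
#'   link overlap + 1 (SPAdes-style graphs), else left `NA`
#' @return an `assembly_graph`
#' @export
load_gfa <- function(path, k = NULL) {
  lines <- readLines(path)
  segs <- character()
  lf <- character(); lfo <- character(); lt <- character(); lto <- character()
  lov <- integer()
  other <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "S") {
      if (length(f) < 3 || !nzchar(f[3]) || f[3] == "*") {
        stop("malformed S line at line ", i, " of ", path)
      }
      segs[[f[2]]] <- f[3]
    } else if (rec == "L") {
      if (length(f) < 6 ||
          !(f[3] %in% c("+", "-")) || !(f[5] %in% c("+", "-"))) {
        stop("malformed L line at line ", i, " of ", path)
      }
      ov <- f[6]
      if (ov == "*") {
        o <- 0L
      } else if (grepl("^[0-9]+M$", ov)) {
        o <- as.integer(sub("M$", "", ov))
      } else {
        stop("unsupported link overlap CIGAR '", ov, "' at line ", i,
             " of ", path)
      }
      lf <- c(lf, f[2]); lfo <- c(lfo, f[3])
      lt <- c(lt, f[4]); lto <- c(lto, f[5])
      lov <- c(lov, o)
    } else if (rec == "H") {
      # header: ignored
    } else {
      other <- c(other, rec)
    }
  }
  if (length(other)) {
    warning("ignored GFA line types: ", paste(unique(other), collapse = ", "))
  }
  if (length(segs) == 0) {
    return(assembly_graph(setNames(character(), character()),
                          k = if (is.null(k)) NA_integer_ else k))
  }
  miss <- setdiff(c(lf, lt), names(segs))
  if (length(miss)) stop("link references missing segment: ", miss[1])
  links <- if (length(lf)) {
    tibble(from = lf, from_orient = lfo, to = lt, to_orient = lto,
           overlap = lov)
  } else NULL
  if (is.null(k)) {
    k <- if (length(lov) && all(lov == lov[1]) && lov[1] > 0) {
      lov[1] + 1L
    } else NA_integer_
  }
  assembly_graph(segs, links, k = k)
}

#' Write an assembly graph as GFA 1.x
#' @param g an `assembly_graph`
#' @param path output file
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  fwd <- g$edges[g$edges$orient == "+", ]
  writeLines(paste("S", fwd$segment, fwd$label, sep = "\t"), con)
  if (nrow(g$links)) {
    fn <- g$edges$segment[g$links$from]
    fo <- g$edges$orient[g$links$from]
    tn <- g$edges$segment[g$links$to]
    to <- g$edges$orient[g$links$to]
    key <- paste(fn, fo, tn, to)
    flip <- function(o) ifelse(o == "+", "-", "+")
    mirror <- paste(tn, flip(to), fn, flip(fo))
    keep <- key <= mirror  # one line per link pair
    writeLines(paste("L", fn[keep], fo[keep], tn[keep], to[keep],
                     paste0(g$links$overlap[keep], "M"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read sequences from FASTA/FASTQ as a named character vector
#' @param path file path
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by default
#' @export
read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path)) "fastq" else "fasta"
  }
  ss <- if (format == "fastq") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readBStringSet(path)
  }
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Import externally produced anchors from a PAF file
#'
#' Maps PAF records onto the doubled graph: a reverse-strand record becomes
#' an anchor on the `-` edge of the target segment, with coordinates
#' mirrored. Imported anchors go through [filter_anchors()] exactly like
#' internally generated ones.
#'
#' @param path PAF file
#' @param g an `assembly_graph` whose segment names match the PAF targets
#' @param query restrict to records of this query name (default: all)
#' @return an anchor tibble
#' @export
read_paf_anchors <- function(path, g, query = NULL) {
  lines <- readLines(path)
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("malformed PAF record: ", substr(ln, 1, 60))
    tibble(
      qname = f[1], qs = as.integer(f[3]), qe = as.integer(f[4]),
      strand = f[5], target = f[6], tlen = as.integer(f[7]),
      ts = as.integer(f[8]), te = as.integer(f[9])
    )
  })
  p <- bind_rows(rows)
  if (!is.null(query)) p <- p[p$qname == query, ]
  orient <- ifelse(p$strand == "+", "+", "-")
  edge <- resolve_edge(g, paste0(p$target, orient))
  es <- ifelse(p$strand == "+", p$ts, p$tlen - p$te)
  ee <- ifelse(p$strand == "+", p$te, p$tlen - p$ts)
  anchor_tibble(g, edge, p$qs, p$qe, as.integer(es), as.integer(ee))
}

#' Write nucleotide alignments as TSV
#'
#' One row per alignment: query name, query start/end/length, start and end
#' positions (edge id, offset), comma-separated oriented edge names, path
#' length in bp, identity (4 decimals) and cigar.
#'
#' @param aln tibble from [align_nt()]
#' @param path output file
#' @export
write_alignments_tsv <- function(aln, path) {
  out <- tibble(
    query = aln$query,
    q_start = aln$qstart, q_end = aln$qend, q_len = aln$qlen,
    start_edge = aln$start_edge, start_offset = aln$start_offset,
    end_edge = aln$end_edge, end_offset = aln$end_offset,
    path = aln$path, path_length = aln$path_length,
    identity = sprintf("%.4f", aln$identity),
    cigar = aln$cigar
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments in GAF
#'
#' Standard GAF columns; the path is written as `>`/`<`-oriented segment
#' names, and the cigar is carried in a `cg:Z:` tag.
#'
#' @param aln tibble from [align_nt()]
#' @param path output file
#' @export
write_gaf <- function(aln, path) {
  if (nrow(aln) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gaf_path <- vapply(strsplit(aln$path, ",", fixed = TRUE), function(p) {
    orient <- ifelse(grepl("-$", p), "<", ">")
    paste0(orient, sub("[+-]$", "", p), collapse = "")
  }, character(1))
  matches <- aln$n_match
  block <- aln$n_match + aln$n_mismatch + aln$n_ins + aln$n_del
  lines <- paste(
    aln$query, aln$qlen, aln$qstart, aln$qend, "+",
    gaf_path, aln$path_full_length, aln$start_offset,
    aln$start_offset + aln$path_length, matches, block, 255L,
    paste0("cg:Z:", aln$cigar),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
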