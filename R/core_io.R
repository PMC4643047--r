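# Readers/writers for the standard flat formats the pipeline consumes and the
# shared coordinate model. Internal coordinates are 0-based half-open on the
# forward strand everywhere; RepeatMasker .out and BLAST tabular (both
# 1-based inclusive) and BED (0-based half-open) are converted at the I/O
# boundary only.

#' Read a genome FASTA file
#'
#' Sequences are uppercased and any character outside \{A,C,G,T,N\}
#' (IUPAC ambiguity codes, gaps left by assembly pipelines) is collapsed to
#' `N`; the number of collapsed characters is reported as a warning so that
#' heavily degenerate inputs are noticed.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of uppercase DNA strings, one per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0L) stop("FASTA parse error in '", path, "': no records")
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate contig id in '", path, "'")
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in '", path, "'")
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " non-ACGTN character(s) mapped to N in '", path, "'")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read RepeatMasker positional output
#'
#' Parses the classic RepeatMasker `.out` dialect: three header lines, then
#' whitespace-separated rows. Genomic coordinates (1-based inclusive) are
#' converted to 0-based half-open. For minus-strand ("C") hits RepeatMasker
#' reports the consensus coordinates as `(left) end begin`; these are
#' normalised so that `cons_start <= cons_end` always holds and
#' `cons_end + cons_left` equals the consensus length.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return a data frame of repeat hits with columns `score`, `contig`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `family_id`,
#'   `cons_start`, `cons_end` (1-based inclusive on the consensus) and
#'   `cons_left` (bp of consensus beyond `cons_end`).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("RepeatMasker .out parse error: fewer than 3 header lines")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(
    score = numeric(0), contig = character(0), start = integer(0),
    end = integer(0), strand = character(0), family_id = character(0),
    cons_start = integer(0), cons_end = integer(0), cons_left = integer(0),
    stringsAsFactors = FALSE
  )
  if (length(body) == 0L) return(empty)
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop("RepeatMasker .out parse error at line ", i + 3L,
           ": expected >= 14 fields, got ", length(f))
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    if (strand == "+") {
      cs <- as.integer(f[12]); ce <- as.integer(f[13]); cl <- strip_paren(f[14])
    } else {
      # minus strand: fields are (left) end begin
      cl <- strip_paren(f[12]); ce <- as.integer(f[13]); cs <- as.integer(f[14])
    }
    if (is.na(cs) || is.na(ce) || cs > ce)
      stop("RepeatMasker .out parse error at line ", i + 3L,
           ": inconsistent consensus coordinates")
    data.frame(
      score = as.numeric(f[1]), contig = f[5],
      start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
      strand = strand, family_id = f[10],
      cons_start = cs, cons_end = ce, cons_left = cl,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write repeat hits in RepeatMasker `.out` layout
#'
#' Inverse of [read_repeatmasker_out()]: emits the three header lines and one
#' whitespace-separated row per hit, restoring the dialect's 1-based inclusive
#' genomic coordinates and the `(left) end begin` consensus-field order for
#' minus-strand hits.
#'
#' @param hits a repeat-hit data frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_repeatmasker_out <- function(hits, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat        position in repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat   class/family  begin end (left)",
    ""
  )
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (h$strand == "+") {
      cons <- sprintf("%d %d (%d)", h$cons_start, h$cons_end, h$cons_left)
      st <- "+"
    } else {
      cons <- sprintf("(%d) %d %d", h$cons_left, h$cons_end, h$cons_start)
      st <- "C"
    }
    sprintf("%6.0f  0.0  0.0  0.0  %s  %d %d (0) %s %s LTR/ERV1 %s 1",
            h$score, h$contig, h$start + 1L, h$end, st, h$family_id, cons)
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read tabular homology-search hits (BLAST outfmt 6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Subject coordinates are converted to the internal
#' 0-based half-open forward-strand convention; hits with `sstart > send`
#' are recorded on the `-` strand.
#'
#' @param path path to a 12-column tab-separated hit table.
#' @return a data frame of search hits with columns `query_id`, `contig`,
#'   `sstart`, `send` (0-based half-open), `strand`, `pident` (fraction in
#'   \[0,1\]), `aln_len`, `qstart`, `qend` (0-based half-open on the query),
#'   `evalue` and `score`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("qseqid", "sseqid", "pident", "length",
                                        "mismatch", "gapopen", "qstart", "qend",
                                        "sstart", "send", "evalue", "bitscore"))
  minus <- tb$sstart > tb$send
  s1 <- ifelse(minus, tb$send, tb$sstart)
  s2 <- ifelse(minus, tb$sstart, tb$send)
  data.frame(
    query_id = tb$qseqid, contig = tb$sseqid,
    sstart = as.integer(s1) - 1L, send = as.integer(s2),
    strand = ifelse(minus, "-", "+"),
    pident = tb$pident / 100, aln_len = as.integer(tb$length),
    qstart = as.integer(tb$qstart) - 1L, qend = as.integer(tb$qend),
    evalue = tb$evalue, score = tb$bitscore,
    stringsAsFactors = FALSE
  )
}

#' Write classified ERV loci as BED6
#'
#' One line per locus spanning its full extent (both LTRs for a provirus),
#' 0-based half-open, matching the internal convention exactly.
#'
#' @param loci an ERV locus table as returned by [pair_ltrs()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(loci, path) {
  if (nrow(loci) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(loci$start < loci$end))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   loci$contig, loci$start, loci$end, loci$locus_id,
                   loci$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of ERV loci
#'
#' @param path path to a BED6 file written by [write_bed()].
#' @return a data frame with columns `contig`, `start`, `end`, `locus_id`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), locus_id = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(contig = f[, 1], start = as.integer(f[, 2]),
             end = as.integer(f[, 3]), locus_id = f[, 4],
             score = as.numeric(f[, 5]), strand = f[, 6],
             stringsAsFactors = FALSE)
}
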