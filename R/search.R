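# Internal homology-search backend: exact k-mer seeds on both strands
# followed by ungapped diagonal extension (maximum-scoring segment). Desk
# scale: genomes are held in memory and indexed per call. The orthology
# logic only consumes the hit-table contract, so an external BLAST tabular
# file can be supplied instead (see read_blast_tab()).

#' Build a k-mer index of a genome
#'
#' @param genome named character vector of contig sequences.
#' @param k seed length in bp (default 16).
#' @return an index object for [search_probe()].
#' @export
kmer_index <- function(genome, k = 16L) {
  idx <- lapply(genome, function(seq) {
    L <- nchar(seq)
    if (L < k) return(character(0))
    substring(seq, 1:(L - k + 1L), k:L)
  })
  structure(list(kmers = idx, genome = genome, k = k), class = "kmer_index")
}

# Maximum-scoring contiguous segment of a +1 (match) / -mismatch_penalty
# score vector (Kadane). Returns c(start, end) 1-based inclusive, or NULL.
max_segment <- function(match, mismatch_penalty = 2) {
  sc <- ifelse(match, 1, -mismatch_penalty)
  best <- 0; best_s <- 0L; best_e <- -1L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_s <- i }
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  if (best_e < best_s) return(NULL)
  c(best_s, best_e)
}

#' Search a probe sequence against an indexed genome
#'
#' Finds exact `k`-mer seed matches on both strands, groups them by
#' diagonal, and extends each diagonal ungapped to its maximum-scoring
#' segment (match +1, mismatch -2). Hit query coordinates are reported in
#' probe orientation; subject coordinates on the target forward strand.
#'
#' @param probe probe DNA string.
#' @param index a [kmer_index()] of the target genome.
#' @param min_len minimum reported segment length in bp (default 30).
#' @param min_ident minimum segment identity (default 0.75).
#' @param query_id query label copied into the hit table.
#' @return a search-hit data frame (columns as in [read_blast_tab()]).
#' @export
search_probe <- function(probe, index, min_len = 30L, min_ident = 0.75,
                         query_id = "probe") {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  out <- list()
  Lq <- nchar(probe)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") probe else revcomp(probe)
    if (Lq < k) next
    qk <- substring(q, 1:(Lq - k + 1L), k:Lq)
    qc <- seq_chars(q)
    for (contig in names(index$kmers)) {
      tk <- index$kmers[[contig]]
      if (length(tk) == 0L) next
      tpos <- which(tk %in% qk)
      if (length(tpos) == 0L) next
      qpos <- match(tk[tpos], qk)  # first probe occurrence of the k-mer
      diags <- unique(tpos - qpos)
      tseq <- index$genome[[contig]]
      Lt <- nchar(tseq)
      tc <- seq_chars(tseq)
      for (d in diags) {
        i_lo <- max(1L, 1L - d)
        i_hi <- min(Lq, Lt - d)
        if (i_hi - i_lo + 1L < min_len) next
        ii <- i_lo:i_hi
        m <- qc[ii] == tc[ii + d]
        seg <- max_segment(m)
        if (is.null(seg)) next
        qs <- ii[seg[1]]; qe <- ii[seg[2]]       # 1-based inclusive in q
        len <- qe - qs + 1L
        if (len < min_len) next
        ident <- mean(m[seg[1]:seg[2]])
        if (ident < min_ident) next
        score <- sum(m[seg[1]:seg[2]]) - 2 * sum(!m[seg[1]:seg[2]])
        ts <- qs + d; te <- qe + d               # 1-based inclusive target
        if (strand == "+") {
          pqs <- qs; pqe <- qe
        } else {                                  # map back to probe orientation
          pqs <- Lq - qe + 1L; pqe <- Lq - qs + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          query_id = query_id, contig = contig,
          sstart = ts - 1L, send = te,
          strand = strand, pident = ident, aln_len = len,
          qstart = pqs - 1L, qend = pqe,
          evalue = NA_real_, score = score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(query_id = character(0), contig = character(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), pident = numeric(0),
                      aln_len = integer(0), qstart = integer(0),
                      qend = integer(0), evalue = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  # collapse duplicate segments found from overlapping diagonals
  hits <- hits[!duplicated(hits[, c("contig", "sstart", "send", "strand")]), ]
  hits[order(-hits$score), , drop = FALSE]
}
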