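# Classification of repeat-annotation hits into ERV loci: complete solo LTRs
# and putative full-length proviruses (two same-strand LTRs separated by
# 3-10 kb of intervening sequence), plus the family-membership and
# cross-species screening filters.

#' Test whether an LTR hit is a complete solo LTR
#'
#' A hit is complete when it misses less than 150 bp at the consensus 5'
#' terminus and less than 10 bp at the consensus 3' terminus. The 5'/3'
#' termini are defined on the consensus, regardless of genomic strand.
#'
#' @param hits a repeat-hit data frame (see [read_repeatmasker_out()]); only
#'   `cons_start` and `cons_end` are used.
#' @param consensus_len length of the LTR consensus in bp.
#' @return a logical vector, one element per hit.
#' @export
is_complete_solo_ltr <- function(hits, consensus_len) {
  stopifnot(consensus_len >= 1)
  if (any(hits$cons_end > consensus_len))
    stop("hit consensus coordinates exceed consensus length (",
         consensus_len, ")")
  (hits$cons_start - 1L) < 150L & (consensus_len - hits$cons_end) < 10L
}

#' Merge fragmented hits of the same LTR family
#'
#' RepeatMasker routinely splits one element copy across several rows. Hits
#' of the same family, contig and strand are merged into one hit covering
#' their union when their genomic intervals either overlap by more than
#' `min_frac` of the shorter hit, or are fragments of one copy: separated by
#' at most `max_join` bp with approximately contiguous consensus
#' coordinates. Consensus coordinates take the extremes and scores are
#' summed.
#'
#' @param hits a repeat-hit data frame.
#' @param min_frac minimum overlap fraction (of the shorter hit) for
#'   merging overlapping rows. Default 0.5.
#' @param max_join maximum genomic gap between consensus-contiguous
#'   fragments. Default 50 bp.
#' @return a repeat-hit data frame with merged rows.
#' @export
merge_ltr_hits <- function(hits, min_frac = 0.5, max_join = 50L) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(hits$contig, hits$strand, hits$start), , drop = FALSE]
  keep <- list()
  cur <- hits[1, , drop = FALSE]
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, , drop = FALSE]
    same <- h$contig == cur$contig && h$strand == cur$strand &&
      h$family_id == cur$family_id
    ov <- min(cur$end, h$end) - max(cur$start, h$start)
    shorter <- min(cur$end - cur$start, h$end - h$start)
    # consensus contiguity runs with the genome on '+', against it on '-'
    cons_step <- if (cur$strand == "+") abs(h$cons_start - cur$cons_end)
                 else abs(cur$cons_start - h$cons_end)
    contiguous <- ov >= -max_join && cons_step <= max_join
    if (same && (ov > min_frac * shorter || contiguous)) {
      cur$start <- min(cur$start, h$start)
      cur$end <- max(cur$end, h$end)
      cur$cons_start <- min(cur$cons_start, h$cons_start)
      cur$cons_end <- max(cur$cons_end, h$cons_end)
      cur$cons_left <- min(cur$cons_left, h$cons_left)
      cur$score <- cur$score + h$score
    } else {
      keep[[length(keep) + 1L]] <- cur
      cur <- h
    }
  }
  keep[[length(keep) + 1L]] <- cur
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

# Maximum-cardinality pairing of LTR hits on one contig/strand group.
# Hits are sorted by start; an (i, j) pair is eligible when the intervening
# gap start_j - end_i lies in [min_gap, max_gap]. Among maximum matchings the
# leftmost hit is paired with its nearest eligible partner (deterministic).
# Exact search with memoisation per connected component; components larger
# than `max_exact` fall back to leftmost-nearest greedy.
pair_hits_max <- function(starts, ends, min_gap, max_gap, max_exact = 15L) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  eligible <- function(i, j) {
    g <- starts[j] - ends[i]
    g >= min_gap && g <= max_gap
  }
  partner <- rep(NA_integer_, n)
  # connected components of the eligibility graph (BFS)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (root in seq_len(n)) {
    if (!is.na(comp[root])) next
    cid <- cid + 1L
    queue <- root
    comp[root] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (!is.na(comp[b])) next
        if (eligible(min(a, b), max(a, b))) {
          comp[b] <- cid
          queue <- c(queue, b)
        }
      }
    }
  }
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1L) next
    if (length(idx) > max_exact) {
      # greedy fallback: leftmost unpaired with nearest eligible partner
      avail <- rep(TRUE, length(idx))
      for (a in seq_along(idx)) {
        if (!avail[a]) next
        cands <- which(avail & seq_along(idx) > a)
        cands <- cands[vapply(cands, function(b)
          eligible(idx[a], idx[b]), logical(1))]
        if (length(cands) > 0L) {
          b <- cands[1]  # nearest downstream
          partner[idx[a]] <- idx[b]; partner[idx[b]] <- idx[a]
          avail[a] <- FALSE; avail[b] <- FALSE
        }
      }
      next
    }
    memo <- new.env(parent = emptyenv())
    best <- function(rem) {
      if (length(rem) < 2L) return(list(count = 0L, pairs = NULL))
      key <- paste(rem, collapse = ",")
      if (!is.null(memo[[key]])) return(memo[[key]])
      a <- rem[1]
      cands <- rem[-1][vapply(rem[-1], function(b) eligible(a, b), logical(1))]
      res <- list(count = -1L, pairs = NULL)
      for (b in cands) {    # nearest partner first; strict > keeps it on ties
        sub <- best(setdiff(rem, c(a, b)))
        if (sub$count + 1L > res$count)
          res <- list(count = sub$count + 1L,
                      pairs = rbind(c(a, b), sub$pairs))
      }
      # leaving the leftmost hit unpaired only wins with strictly more pairs
      skip <- best(rem[-1])
      if (skip$count > res$count) res <- skip
      memo[[key]] <- res
      res
    }
    res <- best(idx)
    if (!is.null(res$pairs))
      for (r in seq_len(nrow(res$pairs))) {
        partner[res$pairs[r, 1]] <- res$pairs[r, 2]
        partner[res$pairs[r, 2]] <- res$pairs[r, 1]
      }
  }
  partner
}

#' Pair LTR hits into proviruses and classify remaining hits as solo LTRs
#'
#' Two LTR hits on the same contig and strand separated by 3-10 kb of
#' intervening sequence (measured between the end of the upstream LTR and the
#' start of the downstream LTR, bounds inclusive) delimit a putative
#' full-length provirus. Fragmented hits are merged first (see
#' [merge_ltr_hits()]). Pairing maximises the number of proviruses; among
#' maximum pairings the leftmost hit takes its nearest eligible partner.
#' Unpaired hits that pass the completeness rule become solo LTRs; incomplete
#' unpaired hits are dropped with a message.
#'
#' @param hits a repeat-hit data frame of LTR-family hits on one genome.
#' @param consensus_len LTR consensus length in bp (for the completeness
#'   rule).
#' @param min_gap,max_gap intervening-sequence bounds in bp (default
#'   3000 and 10000).
#' @param merge merge fragmented hits before pairing (default TRUE).
#' @return an ERV locus data frame with columns `locus_id`, `kind`
#'   (`"provirus"` or `"solo_ltr"`), `contig`, `start`, `end` (locus extent,
#'   0-based half-open), `strand`, `family_id`, `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end` (NA for solo LTRs) and `internal_gap_bp`.
#'   For minus-strand proviruses the element's 5' LTR is the genomically
#'   rightmost one.
#' @export
pair_ltrs <- function(hits, consensus_len, min_gap = 3000L, max_gap = 10000L,
                      merge = TRUE) {
  empty <- data.frame(
    locus_id = character(0), kind = character(0), contig = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    family_id = character(0), ltr5_start = integer(0), ltr5_end = integer(0),
    ltr3_start = integer(0), ltr3_end = integer(0),
    internal_gap_bp = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(hits) == 0L) return(empty)
  if (merge) hits <- merge_ltr_hits(hits)
  hits <- hits[order(hits$contig, hits$strand, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  out <- list()
  dropped <- 0L
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$contig, hits$strand, sep = "\r"))
  for (g in groups) {
    h <- hits[g, , drop = FALSE]
    partner <- pair_hits_max(h$start, h$end, min_gap, max_gap)
    used <- rep(FALSE, nrow(h))
    for (i in seq_len(nrow(h))) {
      if (used[i]) next
      j <- partner[i]
      if (!is.na(j) && j > i) {
        used[i] <- TRUE; used[j] <- TRUE
        # element-orientation LTR labels: on '-' strand the genomically
        # rightmost LTR is the element's 5' LTR
        if (h$strand[i] == "+") {
          l5 <- i; l3 <- j
        } else {
          l5 <- j; l3 <- i
        }
        out[[length(out) + 1L]] <- data.frame(
          locus_id = NA_character_, kind = "provirus",
          contig = h$contig[i], start = h$start[i], end = h$end[j],
          strand = h$strand[i], family_id = h$family_id[i],
          ltr5_start = h$start[l5], ltr5_end = h$end[l5],
          ltr3_start = h$start[l3], ltr3_end = h$end[l3],
          internal_gap_bp = h$start[j] - h$end[i],
          stringsAsFactors = FALSE
        )
      }
    }
    for (i in which(!used)) {
      if (is_complete_solo_ltr(h[i, , drop = FALSE], consensus_len)) {
        out[[length(out) + 1L]] <- data.frame(
          locus_id = NA_character_, kind = "solo_ltr",
          contig = h$contig[i], start = h$start[i], end = h$end[i],
          strand = h$strand[i], family_id = h$family_id[i],
          ltr5_start = h$start[i], ltr5_end = h$end[i],
          ltr3_start = NA_integer_, ltr3_end = NA_integer_,
          internal_gap_bp = NA_integer_, stringsAsFactors = FALSE
        )
      } else dropped <- dropped + 1L
    }
  }
  if (length(out) == 0L) {
    if (dropped > 0L) message(dropped, " incomplete unpaired LTR hit(s) dropped")
    return(empty)
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  loci$locus_id <- sprintf("%s_%04d", ifelse(loci$kind == "provirus",
                                             "prov", "solo"),
                           seq_len(nrow(loci)))
  rownames(loci) <- NULL
  if (dropped > 0L) message(dropped, " incomplete unpaired LTR hit(s) dropped")
  loci
}

#' Filter homology-search hits by the 80/80 screening rule
#'
#' Retains hits with at least `min_identity` nucleotide identity covering at
#' least `min_len_frac` of the query, the screen used to exclude non-specific
#' hits when scanning many genomes with one query domain.
#'
#' @param hits a search-hit data frame (see [read_blast_tab()]).
#' @param query_len query length in bp.
#' @param min_identity identity threshold as a fraction (default 0.80).
#' @param min_len_frac alignment-length threshold as a fraction of
#'   `query_len` (default 0.80).
#' @return the retained rows of `hits`.
#' @export
filter_cst_hits <- function(hits, query_len, min_identity = 0.80,
                            min_len_frac = 0.80) {
  stopifnot(query_len >= 1)
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$pident >= min_identity & hits$aln_len >= min_len_frac * query_len
  hits[keep, , drop = FALSE]
}

# Global-alignment identity between two sequences: matches over aligned
# columns, excluding terminal gap columns (so truncated copies are not
# penalised for missing ends).
alignment_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nucleotide_submat(),
    gapOpening = 5, gapExtension = 1
  )
  x <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  y <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  gap <- x == "-" | y == "-"
  # trim terminal gap runs
  inner <- which(!gap)
  if (length(inner) == 0L) return(0)
  cols <- seq(min(inner), max(inner))
  mean(x[cols] == y[cols])
}

#' Test family membership by pairwise alignment identity
#'
#' A candidate belongs to the family when its best global-alignment identity
#' (matches over aligned columns, terminal gaps excluded) to any current
#' member is at least `min_identity` (inclusive).
#'
#' @param candidate_seq candidate DNA string (>= 50 bp).
#' @param members non-empty character vector of member sequences.
#' @param min_identity membership threshold (default 0.80).
#' @return `TRUE` or `FALSE`.
#' @export
assign_family <- function(candidate_seq, members, min_identity = 0.80) {
  stopifnot(length(members) >= 1L)
  if (nchar(candidate_seq) < 50L)
    stop("candidate shorter than 50 bp: refusing family assignment",
         call. = FALSE)
  best <- max(vapply(members, function(m)
    alignment_identity(candidate_seq, m), numeric(1)))
  best >= min_identity
}

#' Tabulate copy numbers by kind and family
#'
#' Mirrors the per-species copy-number summary layout: one row per family
#' with provirus, solo-LTR and total counts.
#'
#' @param loci an ERV locus data frame (see [pair_ltrs()]).
#' @param species species label recorded in the output.
#' @return a data frame with columns `species`, `family_id`, `proviruses`,
#'   `solo_ltrs`, `total`.
#' @export
copy_number <- function(loci, species) {
  if (nrow(loci) == 0L)
    return(data.frame(species = species, family_id = NA_character_,
                      proviruses = 0L, solo_ltrs = 0L, total = 0L,
                      stringsAsFactors = FALSE))
  fams <- sort(unique(loci$family_id))
  rows <- lapply(fams, function(f) {
    sub <- loci[loci$family_id == f, ]
    np <- sum(sub$kind == "provirus")
    ns <- sum(sub$kind == "solo_ltr")
    data.frame(species = species, family_id = f, proviruses = np,
               solo_ltrs = ns, total = np + ns, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
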