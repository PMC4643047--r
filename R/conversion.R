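# Inter-LTR gene conversion detection. For a provirus orthologous in two
# species, the four LTRs (5'/3' x species A/B) form a quartet whose
# unrooted topology is diagnostic: grouping by LTR position (5'A with 5'B)
# is the speciation signal, while grouping by provirus (5'A with 3'A)
# indicates that post-speciation conversion homogenised the LTRs within each
# lineage. The quartet is resolved by the four-point condition on CpG-masked
# K2P distances, with support from a column bootstrap.

# Reference-based progressive merging of sequences into a common set of
# alignment columns: each sequence is globally aligned to the ungapped first
# sequence; insertions relative to the reference open gap columns in all
# previously merged rows.
align_multi <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  if (length(unique(nchar(seqs))) == 1L && !any(grepl("-", seqs, fixed = TRUE)))
    return(seqs)
  msa <- list(seq_chars(seqs[[1]]))
  ref_cols <- which(msa[[1]] != "-")
  for (i in seq_along(seqs)[-1]) {
    aln <- align_pair(chars_seq(msa[[1]][ref_cols]), seqs[[i]])
    ra <- seq_chars(aln$seq_a)
    na <- seq_chars(aln$seq_b)
    new_row <- character(0)
    ref_i <- 0L   # index into ref_cols
    col_i <- 0L   # current column in existing msa
    ins <- list() # columns to insert after position col_i
    row_parts <- character(0)
    out_rows <- lapply(msa, function(r) character(0))
    pos <- 0L
    for (c in seq_along(ra)) {
      if (ra[c] != "-") {
        ref_i <- ref_i + 1L
        upto <- ref_cols[ref_i]
        for (r in seq_along(msa))
          out_rows[[r]] <- c(out_rows[[r]], msa[[r]][(pos + 1L):upto])
        gapfill <- upto - pos - 1L
        new_row <- c(new_row, rep("-", gapfill), na[c])
        pos <- upto
      } else {
        # insertion in the new sequence: a fresh column for everyone
        for (r in seq_along(msa))
          out_rows[[r]] <- c(out_rows[[r]], "-")
        new_row <- c(new_row, na[c])
      }
    }
    L <- length(msa[[1]])
    if (pos < L) {
      for (r in seq_along(msa))
        out_rows[[r]] <- c(out_rows[[r]], msa[[r]][(pos + 1L):L])
      new_row <- c(new_row, rep("-", L - pos))
    }
    msa <- c(out_rows, list(new_row))
    ref_cols <- which(msa[[1]] != "-")
  }
  out <- vapply(msa, chars_seq, character(1))
  names(out) <- names(seqs)
  out
}

# Columns that are part of a CG dinucleotide in the ungapped sequence of any
# row of an aligned set.
cpg_columns <- function(aln_chars) {
  L <- length(aln_chars[[1]])
  mask <- rep(FALSE, L)
  for (x in aln_chars) {
    ung <- which(x != "-")
    s <- x[ung]
    if (length(s) >= 2L) {
      cg <- which(s[-length(s)] == "C" & s[-1] == "G")
      mask[ung[unique(c(cg, cg + 1L))]] <- TRUE
    }
  }
  mask
}

# K2P distance from (usable, transition, transversion) counts; NA when
# saturated or no usable sites.
k2p_from_counts <- function(n, ti, tv) {
  P <- ti / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- -0.5 * log(w1 * sqrt(w2))
  d[!is.finite(d) | w1 <= 0 | w2 <= 0 | n == 0] <- NA_real_
  d
}

#' Resolve the LTR quartet topology of an orthologous provirus pair
#'
#' Computes CpG-masked K2P distances among the four ingroup LTRs and applies
#' the four-point condition: the pairing with the smallest distance sum is
#' the quartet topology. Grouping \{(5'A,3'A),(5'B,3'B)\} (`by_provirus`)
#' indicates gene conversion; \{(5'A,5'B),(3'A,3'B)\} (`by_ltr_position`) is
#' the speciation signal. Support is the proportion of column-bootstrap
#' replicates in which the chosen topology has the strictly smallest sum.
#'
#' @param ltr5_a,ltr3_a,ltr5_b,ltr3_b LTR DNA strings of the orthologous
#'   provirus in species A and B.
#' @param outgroup optional non-orthologous LTR included in the common
#'   alignment (it does not enter the four-point statistic).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @param mask apply CpG masking (default TRUE).
#' @param locus_id label copied to the verdict.
#' @return a one-row data frame: `locus_id`, `topology` (`by_provirus`,
#'   `by_ltr_position`, `by_cross` or `star`), `converted` (TRUE iff
#'   `by_provirus`), `support` in \[0,1\].
#' @export
quartet_topology <- function(ltr5_a, ltr3_a, ltr5_b, ltr3_b, outgroup = NULL,
                             n_boot = 1000L, seed = NULL, mask = TRUE,
                             locus_id = "locus") {
  seqs <- c(l5a = ltr5_a, l3a = ltr3_a, l5b = ltr5_b, l3b = ltr3_b)
  if (!is.null(outgroup)) seqs <- c(seqs, og = outgroup)
  aln <- align_multi(seqs)
  ch <- lapply(aln[1:4], seq_chars)
  L <- length(ch[[1]])
  usable_base <- Reduce(`&`, lapply(ch, is_base))
  if (mask) usable_base <- usable_base & !cpg_columns(ch)
  pairs <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(1, 4), c(2, 3))
  # per-column indicators per pair: usable / transition / transversion
  IND <- matrix(0, nrow = 3L * length(pairs), ncol = L)
  for (p in seq_along(pairs)) {
    x <- ch[[pairs[[p]][1]]]; y <- ch[[pairs[[p]][2]]]
    use <- usable_base
    diff <- use & x != y
    ti <- diff & TI_PARTNER[x] == y
    ti[is.na(ti)] <- FALSE
    IND[3 * p - 2, ] <- as.numeric(use)
    IND[3 * p - 1, ] <- as.numeric(ti)
    IND[3 * p, ] <- as.numeric(diff & !ti)
  }
  sums_from_counts <- function(cnt) {
    # cnt: 18 x B matrix of pair-wise (n, ti, tv) counts
    d <- sapply(seq_along(pairs), function(p)
      k2p_from_counts(cnt[3 * p - 2, ], cnt[3 * p - 1, ], cnt[3 * p, ]))
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    cbind(by_provirus = d[, 1] + d[, 2],
          by_ltr_position = d[, 3] + d[, 4],
          by_cross = d[, 5] + d[, 6])
  }
  point <- sums_from_counts(matrix(rowSums(IND), ncol = 1))
  verdict <- function(topology, converted, support)
    data.frame(locus_id = locus_id, topology = topology,
               converted = converted, support = support,
               stringsAsFactors = FALSE)
  if (any(is.na(point)))
    return(verdict("star", FALSE, 0))
  ord <- order(point[1, ])
  if (point[1, ord[1]] >= point[1, ord[2]] - 1e-12)  # tie: unresolved
    return(verdict("star", FALSE, 0))
  top <- colnames(point)[ord[1]]
  if (!is.null(seed)) set.seed(seed)
  support <- 0
  if (n_boot > 0L) {
    cnt_b <- IND %*% rmultinom(n_boot, size = L, prob = rep(1 / L, L))
    sums_b <- sums_from_counts(cnt_b)
    win <- !is.na(sums_b[, top]) &
      apply(sums_b, 1, function(r) {
        if (any(is.na(r))) return(FALSE)
        r[top] < min(r[setdiff(colnames(point), top)])
      })
    support <- mean(win)
  }
  verdict(top, top == "by_provirus", support)
}

#' Screen orthologous provirus pairs for inter-LTR gene conversion
#'
#' Applies [quartet_topology()] to each case; cases whose LTRs cannot be
#' extracted are skipped with a message.
#'
#' @param cases a list of quartet cases, each a list with elements
#'   `locus_id`, `ltr5_a`, `ltr3_a`, `ltr5_b`, `ltr3_b` and optionally
#'   `outgroup`.
#' @param n_boot bootstrap replicates per case (default 1000).
#' @param seed optional RNG seed.
#' @param mask apply CpG masking (default TRUE).
#' @return a data frame of verdicts with attribute `summary` (counts of
#'   converted / unconverted / star).
#' @export
conversion_screen <- function(cases, n_boot = 1000L, seed = NULL,
                              mask = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (case in cases) {
    seqs <- case[c("ltr5_a", "ltr3_a", "ltr5_b", "ltr3_b")]
    if (any(vapply(seqs, function(s) is.null(s) || !nzchar(s), logical(1)))) {
      message("skipping ", case$locus_id, ": LTR sequence unavailable")
      next
    }
    rows[[length(rows) + 1L]] <- quartet_topology(
      case$ltr5_a, case$ltr3_a, case$ltr5_b, case$ltr3_b,
      outgroup = case$outgroup, n_boot = n_boot, mask = mask,
      locus_id = case$locus_id %||% "locus"
    )
  }
  if (length(rows) == 0L)
    return(data.frame(locus_id = character(0), topology = character(0),
                      converted = logical(0), support = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(converted = sum(out$converted),
                            unconverted = sum(!out$converted &
                                                out$topology != "star"),
                            star = sum(out$topology == "star"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
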