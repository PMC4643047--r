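# Insertion dating from 5'-3' LTR divergence. A provirus integrates with two
# identical LTRs; each LTR then accumulates neutral substitutions
# independently, so the CpG-masked Kimura two-parameter distance between the
# LTRs divided by twice the host neutral substitution rate estimates the
# insertion age. Sliding-window identity profiles across pairwise provirus
# alignments use the same machinery.

#' Globally align two DNA sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -5,
#' gap extend -1) via Biostrings. The exact aligner is not part of the
#' statistics' definitions; an externally produced alignment can be supplied
#' to downstream functions instead.
#'
#' @param a,b DNA strings.
#' @return a pairwise alignment: a list with aligned strings `seq_a` and
#'   `seq_b` of equal length over \{A,C,G,T,N,-\}, class
#'   `"erv_alignment"`.
#' @export
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nucleotide_submat(),
    gapOpening = 5, gapExtension = 1
  )
  aln <- list(seq_a = as.character(Biostrings::alignedPattern(pa)),
              seq_b = as.character(Biostrings::alignedSubject(pa)))
  class(aln) <- "erv_alignment"
  aln
}

.submat_cache <- new.env(parent = emptyenv())
nucleotide_submat <- function() {
  if (is.null(.submat_cache$m))
    .submat_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1)
  .submat_cache$m
}

as_erv_alignment <- function(aln) {
  if (inherits(aln, "erv_alignment")) return(aln)
  if (is.list(aln) && all(c("seq_a", "seq_b") %in% names(aln)))
    aln <- list(seq_a = aln$seq_a, seq_b = aln$seq_b)
  else if (is.character(aln) && length(aln) == 2L)
    aln <- list(seq_a = aln[[1]], seq_b = aln[[2]])
  else stop("not a pairwise alignment")
  if (nchar(aln$seq_a) != nchar(aln$seq_b))
    stop("aligned sequences differ in length")
  class(aln) <- "erv_alignment"
  aln
}

#' Mask CpG dinucleotide sites in a pairwise alignment
#'
#' Methylated CpG sites are hypermutable and inflate apparent divergence, so
#' they are excluded before distance calculation. Every alignment column
#' belonging to a CG dinucleotide in the ungapped sequence of *either* row
#' (mode `"either"`, the default: the ancestral CpG state is unknown, and the
#' decayed state TG/CA still marks a former CpG in the partner) or of the
#' first row only (mode `"first"`) is replaced by `N` in both rows.
#'
#' @param aln a pairwise alignment (see [align_pair()]).
#' @param mode `"either"` or `"first"`.
#' @return the masked alignment.
#' @export
mask_cpg <- function(aln, mode = c("either", "first")) {
  aln <- as_erv_alignment(aln)
  mode <- match.arg(mode)
  rows <- if (mode == "either") c("seq_a", "seq_b") else "seq_a"
  a <- seq_chars(aln$seq_a)
  b <- seq_chars(aln$seq_b)
  mask <- rep(FALSE, length(a))
  for (r in rows) {
    x <- if (r == "seq_a") a else b
    ung <- which(x != "-")
    s <- x[ung]
    if (length(s) >= 2L) {
      cg <- which(s[-length(s)] == "C" & s[-1] == "G")
      cols <- ung[unique(c(cg, cg + 1L))]
      mask[cols] <- TRUE
    }
  }
  a[mask & a != "-"] <- "N"
  b[mask & b != "-"] <- "N"
  out <- list(seq_a = chars_seq(a), seq_b = chars_seq(b))
  class(out) <- "erv_alignment"
  out
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' Columns containing a gap or `N` in either row are skipped. With transition
#' proportion P and transversion proportion Q over usable sites, the
#' corrected distance is d = -1/2 ln\[(1 - 2P - Q) sqrt(1 - 2Q)\]
#' (substitutions per site).
#'
#' @param aln a pairwise alignment.
#' @param min_sites usable-site count below which the estimate is flagged
#'   low-confidence (default 50).
#' @return a list with `P`, `Q`, `d`, `usable_sites` and `flags` (character
#'   vector; `"low_confidence"` and/or `"saturated"`; `d` is `NA` when
#'   saturated).
#' @export
k2p <- function(aln, min_sites = 50L) {
  aln <- as_erv_alignment(aln)
  a <- seq_chars(aln$seq_a)
  b <- seq_chars(aln$seq_b)
  use <- is_base(a) & is_base(b)
  n <- sum(use)
  flags <- character(0)
  if (n == 0L)
    return(list(P = NA_real_, Q = NA_real_, d = NA_real_, usable_sites = 0L,
                flags = "low_confidence"))
  x <- a[use]; y <- b[use]
  diff <- x != y
  ti <- diff & (TI_PARTNER[x] == y)
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  if (n < min_sites) flags <- c(flags, "low_confidence")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    flags <- c(flags, "saturated")
    d <- NA_real_
  } else {
    d <- -0.5 * log(w1 * sqrt(w2))
  }
  list(P = P, Q = Q, d = d, usable_sites = n, flags = flags)
}

#' Convert an LTR-LTR divergence into an insertion age
#'
#' `age = d / (2 * rate_per_year)`: both LTRs accumulate substitutions
#' independently from identical copies at integration, so the pairwise
#' distance grows at twice the per-lineage rate.
#'
#' @param d K2P distance between the two LTRs (substitutions/site).
#' @param rate_per_year host neutral substitution rate per year.
#' @return age in years.
#' @export
ltr_age_years <- function(d, rate_per_year) {
  stopifnot(rate_per_year > 0)
  d / (2 * rate_per_year)
}

#' Estimate a provirus insertion age from LTR-LTR divergence
#'
#' Extracts the two LTRs of a provirus locus, aligns them, masks CpG sites,
#' computes the K2P distance d and converts it to years as
#' `age = d / (2 * rate_per_year)`; the factor two reflects both LTRs
#' accumulating substitutions independently since insertion.
#'
#' @param locus one row of an ERV locus data frame with `kind == "provirus"`.
#' @param genome named character vector of contig sequences.
#' @param rate_per_year host neutral substitution rate (substitutions per
#'   site per year), e.g. 2.7e-9 for vesper bats, 1.8e-9 for felids, 2.2e-9
#'   as a mammalian average.
#' @param mask apply CpG masking before the distance (default TRUE).
#' @return a list with `locus_id`, `P`, `Q`, `d`, `usable_sites`, `flags`
#'   and `age_years` (`NA` when saturated or too few usable sites).
#' @export
date_provirus <- function(locus, genome, rate_per_year, mask = TRUE) {
  stopifnot(locus$kind == "provirus", rate_per_year > 0)
  seq <- genome[[locus$contig]]
  ltr5 <- subseq0(seq, locus$ltr5_start, locus$ltr5_end)
  ltr3 <- subseq0(seq, locus$ltr3_start, locus$ltr3_end)
  if (locus$strand == "-") {
    ltr5 <- revcomp(ltr5)
    ltr3 <- revcomp(ltr3)
  }
  aln <- align_pair(ltr5, ltr3)
  if (mask) aln <- mask_cpg(aln)
  k <- k2p(aln)
  age <- if (is.na(k$d) || "low_confidence" %in% k$flags) NA_real_
         else ltr_age_years(k$d, rate_per_year)
  c(list(locus_id = locus$locus_id), k, list(age_years = age))
}

#' Date every provirus in a locus table
#'
#' @param loci an ERV locus data frame.
#' @param genome named character vector of contig sequences.
#' @param rate_per_year host neutral substitution rate per year.
#' @param mask apply CpG masking (default TRUE).
#' @return a data frame with one row per provirus: `locus_id`,
#'   `usable_sites`, `P`, `Q`, `d`, `age_my` (age in million years) and
#'   `flags` (comma-separated).
#' @export
date_proviruses <- function(loci, genome, rate_per_year, mask = TRUE) {
  prov <- loci[loci$kind == "provirus", , drop = FALSE]
  rows <- lapply(seq_len(nrow(prov)), function(i) {
    r <- date_provirus(prov[i, ], genome, rate_per_year, mask = mask)
    data.frame(locus_id = r$locus_id, usable_sites = r$usable_sites,
               P = r$P, Q = r$Q, d = r$d, age_my = r$age_years / 1e6,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(locus_id = character(0), usable_sites = integer(0),
                      P = numeric(0), Q = numeric(0), d = numeric(0),
                      age_my = numeric(0), flags = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Sliding-window identity profile along a pairwise alignment
#'
#' The alignment is split into windows of `window` alignment columns advanced
#' by `step`; the last partial window is dropped. Per window the raw identity
#' (matches over usable columns) and the K2P-corrected identity
#' (1 - d) are reported.
#'
#' @param aln a pairwise alignment.
#' @param window window size in alignment columns (default 300).
#' @param step step size in alignment columns (default 50).
#' @return a data frame with one row per window: `window_start` (0-based
#'   alignment column), `window_mid`, `identity`, `k2p_identity` (`NA` when
#'   the window is saturated).
#' @export
sliding_identity <- function(aln, window = 300L, step = 50L) {
  aln <- as_erv_alignment(aln)
  L <- nchar(aln$seq_a)
  a <- seq_chars(aln$seq_a)
  b <- seq_chars(aln$seq_b)
  if (L < window) {
    warning("alignment shorter than one window; using a single ",
            "whole-alignment window")
    window <- L
  }
  starts <- seq(0L, L - window, by = step)
  rows <- lapply(starts, function(s) {
    cols <- (s + 1L):(s + window)
    use <- is_base(a[cols]) & is_base(b[cols])
    ident <- if (sum(use) == 0L) NA_real_
             else mean(a[cols][use] == b[cols][use])
    k <- k2p(list(seq_a = chars_seq(a[cols]), seq_b = chars_seq(b[cols])),
             min_sites = 1L)
    data.frame(window_start = s, window_mid = s + window / 2,
               identity = ident,
               k2p_identity = if (is.na(k$d)) NA_real_ else 1 - k$d)
  })
  do.call(rbind, rows)
}
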