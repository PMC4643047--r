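# Per-domain selection and ORF-integrity statistics. dN/dS is estimated by
# Nei-Gojobori (1986) counting: synonymous/nonsynonymous sites per codon from
# the nine single-base neighbours (changes to stop codons excluded,
# per-position normalisation), observed differences averaged over the
# shortest mutational paths that avoid stop codons, Jukes-Cantor correction
# of the proportions, and a two-sided codon-column bootstrap test of
# omega = 1. Integrity counts in-frame stop codons and frameshift indel runs
# per codon with exact Poisson confidence intervals.

# standard genetic code, hardcoded (the test oracle translates independently)
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

translate_codon <- function(codon) GENETIC_CODE_TABLE[[codon]]

codon_neighbours <- function(codon) {
  b <- seq_chars(codon)
  out <- character(0)
  for (pos in 1:3)
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      nb <- b; nb[pos] <- alt
      out <- c(out, chars_seq(nb))
    }
  out
}

.ng_cache <- new.env(parent = emptyenv())

# Synonymous-site count per sense codon: per position, synonymous fraction
# of the non-stop single-base changes; S + N = 3 per codon.
ng_sites <- function() {
  if (!is.null(.ng_cache$S)) return(.ng_cache$S)
  S <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (codon in SENSE_CODONS) {
    aa <- translate_codon(codon)
    b <- seq_chars(codon)
    s <- 0
    for (pos in 1:3) {
      targets <- vapply(setdiff(c("A", "C", "G", "T"), b[pos]), function(alt) {
        nb <- b; nb[pos] <- alt
        chars_seq(nb)
      }, character(1))
      targets <- targets[!(targets %in% STOP_CODONS)]
      if (length(targets) == 0L) next
      s <- s + sum(vapply(targets, translate_codon, character(1)) == aa) /
        length(targets)
    }
    S[codon] <- s
  }
  .ng_cache$S <- S
  S
}

# Path-averaged synonymous/nonsynonymous difference counts for every sense
# codon pair: all orderings of the differing positions, paths through stop
# codons excluded (all paths used if none avoids a stop).
ng_diffs <- function() {
  if (!is.null(.ng_cache$sd)) return(list(sd = .ng_cache$sd, nd = .ng_cache$nd))
  n <- length(SENSE_CODONS)
  sd <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  nd <- sd
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    c1 <- seq_chars(SENSE_CODONS[i]); c2 <- seq_chars(SENSE_CODONS[j])
    pos <- which(c1 != c2)
    if (length(pos) == 0L) next
    perms <- switch(length(pos),
      list(pos),
      list(pos, rev(pos)),
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    )
    paths <- lapply(perms, function(ord) {
      cur <- c1
      steps <- list()
      for (p in ord) {
        nxt <- cur; nxt[p] <- c2[p]
        steps[[length(steps) + 1L]] <- c(chars_seq(cur), chars_seq(nxt))
        cur <- nxt
      }
      steps
    })
    valid <- vapply(paths, function(steps) {
      inter <- vapply(steps, `[`, character(1), 2)
      inter <- inter[-length(inter)]  # endpoints are sense by construction
      !any(inter %in% STOP_CODONS)
    }, logical(1))
    use <- if (any(valid)) paths[valid] else paths
    svals <- vapply(use, function(steps)
      sum(vapply(steps, function(st)
        translate_codon(st[1]) == translate_codon(st[2]), logical(1))),
      numeric(1))
    nvals <- vapply(use, function(steps) length(steps), numeric(1)) - svals
    sd[i, j] <- sd[j, i] <- mean(svals)
    nd[i, j] <- nd[j, i] <- mean(nvals)
  }
  .ng_cache$sd <- sd
  .ng_cache$nd <- nd
  list(sd = sd, nd = nd)
}

jc_correct <- function(p) {
  d <- -0.75 * log(1 - 4 / 3 * p)
  d[p >= 0.75] <- NA_real_
  d
}

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Nei-Gojobori dN/dS with a codon-bootstrap test of neutrality
#'
#' Analysis is restricted to codon columns where every sequence carries a
#' sense codon (no gap, `N` or stop). Synonymous/nonsynonymous sites and
#' path-averaged differences are counted per sequence pair, proportions are
#' Jukes-Cantor corrected, dN and dS are averaged over all pairs and
#' omega = dN/dS. The p-value tests omega = 1 two-sidedly by resampling
#' codon columns.
#'
#' @param aln named character vector of aligned coding sequences (equal
#'   length, divisible by 3, gaps in whole-codon units).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional RNG seed for the bootstrap (deterministic p-value).
#' @param min_codons minimum usable codon columns (default 30; fewer is an
#'   error of class `"ervfossil_too_short"`).
#' @param domain_id,subfamily_id labels copied to the result.
#' @return a list with `dN`, `dS`, `omega`, `p_value`, `verdict`
#'   (`"purifying"` iff omega < 1 and p < 0.05; `"undefined"` when dS = 0),
#'   `n_codons`, `n_pairs` and the labels.
#' @export
ng_dnds <- function(aln, n_boot = 1000L, seed = NULL, min_codons = 30L,
                    domain_id = NA_character_, subfamily_id = NA_character_) {
  stopifnot(length(aln) >= 2L)
  lens <- unique(nchar(aln))
  if (length(lens) != 1L) stop("sequences are not aligned (unequal lengths)")
  cod <- do.call(rbind, lapply(aln, split_codons))
  usable <- apply(cod, 2, function(cc) all(cc %in% SENSE_CODONS))
  if (sum(usable) < min_codons)
    stop(structure(class = c("ervfossil_too_short", "error", "condition"),
                   list(message = paste0("fewer than ", min_codons,
                                         " shared ungapped codons (",
                                         sum(usable), ")"),
                        call = sys.call())))
  cod <- cod[, usable, drop = FALSE]
  C <- ncol(cod)
  S_tab <- ng_sites()
  D <- ng_diffs()
  prs <- utils::combn(nrow(cod), 2)
  P <- ncol(prs)
  SD <- matrix(0, P, C); ND <- SD; SS <- SD; NS <- SD
  for (p in seq_len(P)) {
    c1 <- cod[prs[1, p], ]; c2 <- cod[prs[2, p], ]
    SD[p, ] <- D$sd[cbind(c1, c2)]
    ND[p, ] <- D$nd[cbind(c1, c2)]
    SS[p, ] <- (S_tab[c1] + S_tab[c2]) / 2
    NS[p, ] <- 3 - SS[p, ]
  }
  pair_stats <- function(sd, nd, ss, ns) {
    pS <- sd / ss
    pN <- nd / ns
    list(dS = jc_correct(pS), dN = jc_correct(pN))
  }
  pt <- pair_stats(rowSums(SD), rowSums(ND), rowSums(SS), rowSums(NS))
  dS <- mean(pt$dS, na.rm = TRUE)
  dN <- mean(pt$dN, na.rm = TRUE)
  omega <- if (!is.finite(dS) || dS == 0) NA_real_ else dN / dS
  p_value <- NA_real_
  if (!is.na(omega) && n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    cnt <- rmultinom(n_boot, size = C, prob = rep(1 / C, C))
    sd_b <- SD %*% cnt; nd_b <- ND %*% cnt
    ss_b <- SS %*% cnt; ns_b <- NS %*% cnt
    dS_b <- matrix(jc_correct(as.vector(sd_b / ss_b)), P)
    dN_b <- matrix(jc_correct(as.vector(nd_b / ns_b)), P)
    omega_b <- colMeans(dN_b, na.rm = TRUE) / colMeans(dS_b, na.rm = TRUE)
    omega_b <- omega_b[is.finite(omega_b)]
    B <- length(omega_b)
    if (B > 0L)
      p_value <- min(1, 2 * min((1 + sum(omega_b <= 1)) / (B + 1),
                                (1 + sum(omega_b >= 1)) / (B + 1)))
  }
  verdict <- if (is.na(omega)) "undefined"
             else if (omega < 1 && !is.na(p_value) && p_value < 0.05) "purifying"
             else "neutral_or_relaxed"
  list(domain_id = domain_id, subfamily_id = subfamily_id,
       dN = dN, dS = dS, omega = omega, p_value = p_value,
       verdict = verdict, n_codons = C, n_pairs = P)
}

#' Bootstrap test of omega = 1
#'
#' Convenience wrapper around [ng_dnds()] returning only the two-sided
#' codon-bootstrap p-value; `NA` when omega is undefined (e.g. identical
#' sequences).
#'
#' @inheritParams ng_dnds
#' @param replicates bootstrap replicates (default 1000).
#' @return the p-value.
#' @export
omega_neutrality_test <- function(aln, replicates = 1000L, seed = NULL) {
  ng_dnds(aln, n_boot = replicates, seed = seed)$p_value
}

#' Exact Poisson confidence interval for an event rate
#'
#' Two-sided exact (Garwood) interval for a Poisson count `x` observed over
#' `exposure` units; the zero-count upper bound is -ln(0.025)/exposure.
#'
#' @param x event count.
#' @param exposure exposure (e.g. codons examined).
#' @param conf confidence level (default 0.95).
#' @return c(lower, upper) rate bounds.
#' @export
poisson_ci_exact <- function(x, exposure, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qgamma(a, x) / exposure
  upper <- qgamma(1 - a, x + 1) / exposure
  c(lower = lower, upper = upper)
}

#' ORF integrity: stop-codon and frameshift frequency per codon
#'
#' Each sequence is aligned to the intact domain consensus (pairwise global
#' alignment, unless the inputs are already aligned and of equal length).
#' The reading frame is defined by the consensus. A frameshift event is one
#' contiguous indel run whose length is not a multiple of 3, counted once
#' regardless of length. Stop codons (TAA/TAG/TGA) are counted at consensus
#' codons where the sequence is ungapped and the local frame is intact
#' (cumulative indel offset divisible by 3), so a frameshift does not
#' cascade into spurious downstream stops; a natural terminator in the final
#' consensus codon is excluded. The 95% CI is the exact Poisson interval on
#' the pooled event count with the pooled codon exposure.
#'
#' @param seqs character vector of domain sequences (may contain `-`).
#' @param consensus intact domain consensus (length divisible by 3).
#' @param domain_id,subfamily_id labels copied to the result.
#' @return a list with `n_codons`, `n_stops`, `n_frameshifts`, `freq`,
#'   `ci95` (lower/upper), labels, and `per_seq` (data frame of per-sequence
#'   counts).
#' @export
integrity <- function(seqs, consensus, domain_id = NA_character_,
                      subfamily_id = NA_character_) {
  cons_ung <- gsub("-", "", consensus, fixed = TRUE)
  if (nchar(cons_ung) %% 3 != 0)
    stop("consensus length not divisible by 3: reading frame undeterminable")
  n_cons_codons <- nchar(cons_ung) / 3
  cons_ends_stop <- substr(cons_ung, nchar(cons_ung) - 2, nchar(cons_ung)) %in%
    STOP_CODONS
  per <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (nchar(gsub("-", "", s, fixed = TRUE)) == 0L)
      return(data.frame(n_codons = 0L, n_stops = 0L, n_frameshifts = 0L))
    if (nchar(s) == nchar(consensus) && (grepl("-", s, fixed = TRUE) ||
                                         nchar(s) == nchar(cons_ung))) {
      a <- seq_chars(consensus); b <- seq_chars(s)
    } else {
      aln <- align_pair(cons_ung, gsub("-", "", s, fixed = TRUE))
      a <- seq_chars(aln$seq_a); b <- seq_chars(aln$seq_b)
    }
    gap <- a == "-" | b == "-"
    # frameshift events: contiguous indel runs with length %% 3 != 0
    r <- rle(gap)
    n_fs <- sum(r$values & r$lengths %% 3 != 0)
    # stop codons in the locally restored frame
    cons_pos <- cumsum(a != "-")
    shift <- cumsum((a == "-") - (b == "-"))  # net insertion minus deletion
    n_stop <- 0L
    n_codons_seen <- 0L
    for (ci in seq_len(n_cons_codons)) {
      cols <- which(a != "-" & cons_pos >= (3 * ci - 2) & cons_pos <= 3 * ci)
      if (length(cols) != 3L) next
      if (any(b[cols] == "-")) next
      pre_shift <- if (cols[1] == 1L) 0L else shift[cols[1] - 1L]
      if (pre_shift %% 3 != 0) next
      n_codons_seen <- n_codons_seen + 1L
      codon <- chars_seq(b[cols])
      if (codon %in% STOP_CODONS && !(cons_ends_stop && ci == n_cons_codons))
        n_stop <- n_stop + 1L
    }
    data.frame(n_codons = n_codons_seen, n_stops = n_stop,
               n_frameshifts = n_fs)
  })
  per <- do.call(rbind, per)
  n_codons <- sum(per$n_codons)
  n_events <- sum(per$n_stops) + sum(per$n_frameshifts)
  ci <- poisson_ci_exact(n_events, n_codons)
  list(domain_id = domain_id, subfamily_id = subfamily_id,
       n_codons = n_codons, n_stops = sum(per$n_stops),
       n_frameshifts = sum(per$n_frameshifts),
       freq = n_events / n_codons, ci95 = ci, per_seq = per)
}

#' Cluster shared deletion breakpoints
#'
#' Scans sequences aligned to a common reference for internal deletions of
#' at least `min_del` bp and clusters them by breakpoint coordinates within
#' `tol` bp at each end; clusters shared by at least two sequences are
#' reported (the signature of amplification from a deletion-carrying
#' progenitor).
#'
#' @param seqs character vector of sequences aligned to a common reference
#'   (equal lengths; deletions as `-` runs).
#' @param min_del minimum deletion length in bp (default 100).
#' @param tol breakpoint tolerance in bp (default 10).
#' @return a data frame with one row per shared cluster: `start`, `end`
#'   (0-based alignment columns of the representative deletion) and
#'   `n_sharing`.
#' @export
shared_breakpoints <- function(seqs, min_del = 100L, tol = 10L) {
  dels <- list()
  for (s in seqs) {
    x <- seq_chars(s)
    r <- rle(x == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_del)) {
      if (starts[k] == 1L || ends[k] == length(x)) next  # terminal truncation
      dels[[length(dels) + 1L]] <- c(starts[k] - 1L, ends[k])
    }
  }
  if (length(dels) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      n_sharing = integer(0)))
  dmat <- do.call(rbind, dels)
  reps <- list(); counts <- integer(0)
  for (i in seq_len(nrow(dmat))) {
    hit <- NA_integer_
    for (j in seq_along(reps))
      if (abs(dmat[i, 1] - reps[[j]][1]) <= tol &&
          abs(dmat[i, 2] - reps[[j]][2]) <= tol) { hit <- j; break }
    if (is.na(hit)) {
      reps[[length(reps) + 1L]] <- dmat[i, ]
      counts <- c(counts, 1L)
    } else counts[hit] <- counts[hit] + 1L
  }
  keep <- counts >= 2L
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      n_sharing = integer(0)))
  out <- data.frame(start = vapply(reps[keep], `[`, numeric(1), 1),
                    end = vapply(reps[keep], `[`, numeric(1), 2),
                    n_sharing = counts[keep])
  out[order(-out$n_sharing), , drop = FALSE]
}
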