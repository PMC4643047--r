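# Shared fixture builders. All sequence fixtures are generated in code.

rep_str <- function(x, n) paste(rep(x, n), collapse = "")

# a repeat-hit data frame row in the internal convention
rm_hit <- function(contig = "c1", start, end, strand = "+",
                   family = "LTRX", cons_start = 1L, cons_end = 600L,
                   cons_left = 0L, score = 1000) {
  data.frame(score = score, contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand, family_id = family,
             cons_start = as.integer(cons_start),
             cons_end = as.integer(cons_end),
             cons_left = as.integer(cons_left), stringsAsFactors = FALSE)
}

# hand-rolled RepeatMasker .out text (independent of write_repeatmasker_out)
rm_out_text <- function(rows) {
  c("   SW  perc perc perc  query      position in query     matching repeat",
    "score  div. del. ins.  sequence   begin  end    (left)  repeat  class  begin end (left)",
    "",
    rows)
}

# independent brute-force maximum matching for the pairing property tests
# (enumeration over the first hit's options only, no memoisation)
oracle_max_pairs <- function(starts, ends, lo = 3000, hi = 10000) {
  go <- function(idx) {
    if (length(idx) < 2) return(0)
    best <- go(idx[-1])
    for (j in idx[-1]) {
      gap <- starts[j] - ends[idx[1]]
      if (gap >= lo && gap <= hi)
        best <- max(best, 1 + go(setdiff(idx, c(idx[1], j))))
    }
    best
  }
  go(seq_along(starts))
}

# independent K2P from explicit column counting (test-local oracle)
oracle_k2p <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0) return(NA_real_)
  ti_pairs <- c("AG", "GA", "CT", "TC")
  ti <- sum(paste0(x, y) %in% ti_pairs)
  tv <- sum(x != y) - ti
  P <- ti / n; Q <- tv / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

# least-squares quartet fit: returns the best-fitting of the three pairings
# of taxa (1,2,3,4), given a 4x4 distance matrix (pracma::lsqnonneg)
oracle_ls_quartet <- function(D) {
  d <- c(D[1, 2], D[3, 4], D[1, 3], D[2, 4], D[1, 4], D[2, 3])
  pair_rows <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(1, 4), c(2, 3))
  # columns: external edges e1..e4 (one per taxon) + internal edge e5,
  # which lies on the path between taxa in different cherries
  design <- function(cherry1) {
    t(sapply(pair_rows, function(pr) {
      r <- numeric(5)
      r[pr[1]] <- 1; r[pr[2]] <- 1
      same_cherry <- all(pr %in% cherry1) || all(!(pr %in% cherry1))
      if (!same_cherry) r[5] <- 1
      r
    }))
  }
  fits <- vapply(list(c(1, 2), c(1, 3), c(1, 4)), function(ch) {
    A <- design(ch)
    f <- pracma::lsqnonneg(A, d)
    sum((A %*% f$x - d)^2)
  }, numeric(1))
  c("by_provirus", "by_ltr_position", "by_cross")[which.min(fits)]
}
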