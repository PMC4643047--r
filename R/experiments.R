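# End-to-end validation experiments on synthetic data with known ground
# truth. Each evaluator regenerates its inputs from a seed, runs the
# corresponding pipeline stage, and returns summary quantities. They back
# both the acceptance test suite and scripts/acceptance.R.

#' Brute-force maximum LTR pairing (reference oracle)
#'
#' Plain recursive enumeration of all matchings under the gap window,
#' returning only the maximum number of pairs. Independent of the search
#' used by [pair_ltrs()] (no memoisation, no tie-breaking); intended as a
#' cross-check on small instances.
#'
#' @param starts,ends sorted hit coordinates (0-based half-open).
#' @param min_gap,max_gap intervening-gap window in bp.
#' @return the maximum number of pairs.
#' @export
max_pairing_bruteforce <- function(starts, ends, min_gap = 3000L,
                                   max_gap = 10000L) {
  n <- length(starts)
  recurse <- function(rem) {
    if (length(rem) < 2L) return(0L)
    a <- rem[1]
    best <- recurse(rem[-1])
    for (b in rem[-1]) {
      g <- starts[b] - ends[a]
      if (g >= min_gap && g <= max_gap) {
        cand <- 1L + recurse(setdiff(rem, c(a, b)))
        if (cand > best) best <- cand
      }
    }
    best
  }
  recurse(seq_len(n))
}

#' Annotation-recovery experiment
#'
#' Simulates one genome with planted proviruses and solo LTRs, annotates it
#' from the emitted hit table, and scores recovery against truth; also
#' compares [pair_ltrs()] pair counts to the brute-force maximum on random
#' small hit instances.
#'
#' @param seed RNG seed.
#' @param n_provirus,n_solo planted element counts (defaults 50 and 200).
#' @param n_instances random pairing instances for the oracle comparison.
#' @return a list of summary numbers.
#' @export
eval_annotation <- function(seed, n_provirus = 50L, n_solo = 200L,
                            n_instances = 1000L) {
  cfg <- sim_config(seed = seed, genome_len = 4e6L)
  sim <- sim_annotation_genome(n_provirus, n_solo, cfg)
  loci <- pair_ltrs(sim$rm, consensus_len = cfg$ltr_len)
  key <- function(df) paste(df$start, df$end)
  tp <- sim$truth[sim$truth$kind == "provirus", ]
  rp <- loci[loci$kind == "provirus", ]
  prov_recall <- mean(key(tp) %in% key(rp))
  false_prov <- sum(!(key(rp) %in% key(tp)))
  ts <- sim$truth[sim$truth$kind == "solo_ltr", ]
  rs <- loci[loci$kind == "solo_ltr", ]
  solo_recall <- mean(key(ts) %in% key(rs))
  # oracle comparison on random <= 8-hit instances
  set.seed(seed + 1L)
  agree <- 0L
  for (i in seq_len(n_instances)) {
    n <- sample(2:8, 1)
    starts <- sort(sample.int(30000L, n))
    ends <- starts + 600L
    hits <- data.frame(score = 1, contig = "c", start = starts, end = ends,
                       strand = "+", family_id = "L", cons_start = 1L,
                       cons_end = 600L, cons_left = 0L,
                       stringsAsFactors = FALSE)
    got <- sum(pair_ltrs(hits, consensus_len = 600L, merge = FALSE)$kind ==
                 "provirus")
    want <- max_pairing_bruteforce(starts, ends)
    if (got == want) agree <- agree + 1L
  }
  list(provirus_recall = prov_recall, false_proviruses = false_prov,
       solo_recall = solo_recall,
       pairing_oracle_agreement = agree / n_instances,
       n_provirus = n_provirus, n_solo = n_solo, n_instances = n_instances)
}

#' Dating parameter-recovery experiment
#'
#' Simulates proviruses with 1 kb LTRs at true ages of 1, 5, 10 and 20 MY
#' under the vespertilionid rate and scores the mean estimated age per age
#' class. The recovery cohort plants no CpG effect, so ages are estimated
#' without masking (on random sequence the either-sequence CpG mask
#' preferentially removes substituted columns and would deflate the clock);
#' separately, with 10x CpG hypermutability, CpG-masked and unmasked
#' estimates are compared against truth per replicate.
#'
#' @param seed RNG seed.
#' @param n_per_age replicates per age class (default 500).
#' @param n_cpg replicates for the CpG contrast (default 500).
#' @param rate substitution rate per year (default 2.7e-9).
#' @return a list with per-age mean estimates and relative errors, and the
#'   fraction of CpG replicates where masking is closer to truth.
#' @export
eval_dating <- function(seed, n_per_age = 500L, n_cpg = 500L,
                        rate = 2.7e-9) {
  set.seed(seed)
  ages_my <- c(1, 5, 10, 20)
  mean_est <- numeric(length(ages_my))
  for (k in seq_along(ages_my)) {
    pairs <- sim_ltr_pairs(n_per_age, ages_my[k] * 1e6, ltr_len = 1000L,
                           rate = rate)
    # simulated pairs carry no indels, so they are already aligned
    est <- vapply(pairs, function(p) {
      aln <- list(seq_a = p$ltr5, seq_b = p$ltr3)
      ltr_age_years(k2p(aln)$d, rate) / 1e6
    }, numeric(1))
    mean_est[k] <- mean(est, na.rm = TRUE)
  }
  rel_err <- abs(mean_est - ages_my) / ages_my
  # CpG contrast at 10 MY with 10x hypermutability
  pairs <- sim_ltr_pairs(n_cpg, 1e7, ltr_len = 1000L, rate = rate,
                         cpg_multiplier = 10)
  closer <- vapply(pairs, function(p) {
    aln <- list(seq_a = p$ltr5, seq_b = p$ltr3)
    a_unmasked <- ltr_age_years(k2p(aln)$d, rate) / 1e6
    a_masked <- ltr_age_years(k2p(mask_cpg(aln))$d, rate) / 1e6
    if (is.na(a_masked) || is.na(a_unmasked)) return(NA)
    abs(a_masked - 10) < abs(a_unmasked - 10)
  }, logical(1))
  list(ages_my = ages_my, mean_age_my = mean_est, rel_err = rel_err,
       max_rel_err = max(rel_err),
       frac_masked_closer = mean(closer, na.rm = TRUE),
       n_per_age = n_per_age, n_cpg = n_cpg)
}

#' K2P cross-check against an independent implementation
#'
#' Random ungapped alignments over a range of divergences; the package K2P
#' distance is compared column-for-column against `ape::dist.dna`
#' (model "K80", pairwise deletion).
#'
#' @param seed RNG seed.
#' @param n number of random alignments (default 10000).
#' @return a list with the maximum absolute difference and `n`.
#' @export
eval_k2p_oracle <- function(seed, n = 10000L) {
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n)) {
    L <- sample(60:200, 1)
    anc <- random_dna(L, runif(1, 0.3, 0.7))
    t1 <- runif(1, 0, 0.15)
    a <- mutate_seq(anc, 1, t1, ti_tv = runif(1, 0.5, 4))
    b <- mutate_seq(anc, 1, runif(1, 0, 0.15), ti_tv = runif(1, 0.5, 4))
    d_pkg <- k2p(list(seq_a = a, seq_b = b), min_sites = 1L)$d
    m <- rbind(seq_chars(tolower(a)), seq_chars(tolower(b)))
    d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                      pairwise.deletion = TRUE))
    if (is.na(d_pkg) || is.na(d_ape)) next
    worst <- max(worst, abs(d_pkg - d_ape))
  }
  list(max_abs_diff = worst, n = n)
}

#' Orthology-recovery experiment
#'
#' Simulates a two-species genome pair with ancestral and species-specific
#' insertions (some reduced to solo LTRs), calls orthology in both
#' directions, and scores state calls against truth; absent calls are
#' checked for contiguous flanks and a recoverable 4-bp TSD.
#'
#' @param seed RNG seed.
#' @param n_ancestral,n_specific_a,n_specific_b insertion counts.
#' @param solo_fraction per-lineage solo-LTR probability.
#' @return a list with call accuracy, absent-call contiguity and TSD
#'   recovery fractions, and the per-lineage locus partition.
#' @export
eval_orthology <- function(seed, n_ancestral = 10L, n_specific_a = 10L,
                           n_specific_b = 10L, solo_fraction = 0.15) {
  cfg <- sim_config(seed = seed, genome_len = 8e5L,
                    n_ancestral = n_ancestral, n_specific_a = n_specific_a,
                    n_specific_b = n_specific_b,
                    solo_fraction = solo_fraction)
  sim <- sim_erv_genomes(cfg)
  tr <- sim$truth
  loci_from_truth <- function(side) {
    kind <- tr[[paste0("kind_", side)]]
    keep <- kind != "absent"
    start <- tr[[paste0("start_", side)]][keep]
    end <- tr[[paste0("end_", side)]][keep]
    data.frame(locus_id = tr$locus_id[keep], kind = kind[keep],
               contig = "chrA", start = start, end = end,
               strand = tr$strand[keep], stringsAsFactors = FALSE)
  }
  expected_state <- function(kind) {
    ifelse(kind == "provirus", "present_provirus",
           ifelse(kind == "solo_ltr", "present_solo", "absent_empty"))
  }
  score <- function(donor, target) {
    loci <- loci_from_truth(donor)
    calls <- call_orthology(loci,
                            sim[[paste0("genome_", donor)]],
                            sim[[paste0("genome_", target)]],
                            ltr_len = cfg$ltr_len,
                            target_species = target)
    want <- expected_state(tr[[paste0("kind_", target)]][
      match(calls$locus_id, tr$locus_id)])
    tsd_true <- tr$tsd[match(calls$locus_id, tr$locus_id)]
    ab <- calls$state == "absent_empty"
    list(correct = calls$state == want,
         absent_contiguous = abs(calls$target_end[ab] -
                                   calls$target_start[ab]) <= 25,
         tsd_ok = !is.na(calls$tsd_seq[ab]) &
           calls$tsd_seq[ab] == tsd_true[ab])
  }
  ab_res <- score("a", "b")
  ba_res <- score("b", "a")
  correct <- c(ab_res$correct, ba_res$correct)
  contig <- c(ab_res$absent_contiguous, ba_res$absent_contiguous)
  tsd_ok <- c(ab_res$tsd_ok, ba_res$tsd_ok)
  list(call_accuracy = mean(correct), n_calls = length(correct),
       absent_contiguous_frac = if (length(contig)) mean(contig) else NA,
       tsd_recovered_frac = if (length(tsd_ok)) mean(tsd_ok) else NA,
       n_absent_calls = length(tsd_ok))
}

#' Gene-conversion detection experiment
#'
#' Simulates quartets with and without post-speciation LTR conversion
#' (tract >= 80%) and scores recall and false-positive rate of the quartet
#' topology test at a given support threshold.
#'
#' @param seed RNG seed.
#' @param n quartets (default 500).
#' @param support_min support threshold for calling conversion (default
#'   0.7).
#' @param n_boot bootstrap replicates per quartet (default 1000).
#' @return a list with recall, false-positive rate and cohort sizes.
#' @export
eval_conversion <- function(seed, n = 500L, support_min = 0.7,
                            n_boot = 1000L) {
  set.seed(seed)
  sim <- sim_quartets(n, p_converted = 0.5)
  verdicts <- conversion_screen(sim$cases, n_boot = n_boot)
  called <- verdicts$converted & verdicts$support >= support_min
  truth <- sim$truth
  list(recall = mean(called[truth]),
       fpr = mean(called[!truth]),
       n_converted = sum(truth), n_unconverted = sum(!truth))
}

#' Selection-calibration experiment
#'
#' Simulated codon alignments (star tree, 10 taxa, 300 codons, moderate
#' divergence): mean Nei-Gojobori omega per true omega in \{0.2, 0.5, 1\},
#' and the rejection rate of the omega = 1 bootstrap test at alpha = 0.05
#' under neutral simulation.
#'
#' @param seed RNG seed.
#' @param n_rep replicates per omega for recovery (default 30).
#' @param n_null neutral simulations for calibration (default 200).
#' @param branch_len tip branch length (default 0.1 substitutions/site).
#' @return a list with mean omega estimates, recovery errors and the null
#'   rejection rate.
#' @export
eval_selection <- function(seed, n_rep = 30L, n_null = 200L,
                           branch_len = 0.1) {
  set.seed(seed)
  omegas <- c(0.2, 0.5, 1.0)
  mean_est <- vapply(omegas, function(w) {
    mean(vapply(seq_len(n_rep), function(i) {
      aln <- sim_codon_alignment(10L, 300L, omega = w,
                                 branch_len = branch_len)
      ng_dnds(aln, n_boot = 0L)$omega
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  reject <- vapply(seq_len(n_null), function(i) {
    aln <- sim_codon_alignment(10L, 300L, omega = 1,
                               branch_len = branch_len)
    p <- ng_dnds(aln, n_boot = 1000L)$p_value
    !is.na(p) && p < 0.05
  }, logical(1))
  list(omega_true = omegas, omega_mean = mean_est,
       omega_abs_err = abs(mean_est - omegas),
       max_omega_abs_err = max(abs(mean_est - omegas)),
       null_rejection_rate = mean(reject),
       n_rep = n_rep, n_null = n_null)
}

#' Poisson-interval coverage experiment
#'
#' Draws Poisson event counts at several true per-codon rates and measures
#' the empirical coverage of the exact 95% interval; also evaluates the
#' zero-count upper bound against its closed form.
#'
#' @param seed RNG seed.
#' @param n_draws total simulated counts (default 10000, split over rates).
#' @return a list with overall coverage and the zero-count bound ratio.
#' @export
eval_integrity_ci <- function(seed, n_draws = 10000L) {
  set.seed(seed)
  rates <- c(0.001, 0.004, 0.01, 0.02)
  exposure <- 500
  per <- ceiling(n_draws / length(rates))
  cover <- unlist(lapply(rates, function(r) {
    x <- stats::rpois(per, r * exposure)
    vapply(x, function(xi) {
      ci <- poisson_ci_exact(xi, exposure)
      ci[1] <= r && r <= ci[2]
    }, logical(1))
  }))
  zero_upper <- poisson_ci_exact(0, 1000)[["upper"]]
  list(coverage = mean(cover), n_draws = length(cover),
       zero_upper_1000 = zero_upper,
       zero_upper_closed_form = -log(0.025) / 1000)
}

#' Shared-deletion clustering experiment
#'
#' A 43-member family in which 29 members carry one identical envelope
#' deletion; [shared_breakpoints()] must return exactly one cluster of 29.
#'
#' @param seed RNG seed.
#' @return a list with the number of clusters and the largest cluster size.
#' @export
eval_deletion <- function(seed) {
  set.seed(seed)
  fam <- sim_deletion_family(43L, 29L)
  bp <- shared_breakpoints(fam$seqs)
  list(n_clusters = nrow(bp),
       n_sharing = if (nrow(bp)) max(bp$n_sharing) else 0L)
}

#' Sliding-window bookkeeping experiment
#'
#' Checks the window-count formula floor((L - window)/step) + 1 over a range
#' of alignment lengths and that identical inputs give identity 1 in every
#' window.
#'
#' @param seed RNG seed.
#' @param lengths alignment lengths to test.
#' @return a list with the fraction of lengths matching the formula and the
#'   minimum identity observed on identical inputs.
#' @export
eval_sliding <- function(seed, lengths = seq(300L, 2000L, by = 37L)) {
  set.seed(seed)
  ok <- vapply(lengths, function(L) {
    s <- random_dna(L, 0.5)
    prof <- sliding_identity(list(seq_a = s, seq_b = s))
    nrow(prof) == floor((L - 300) / 50) + 1 && all(prof$identity == 1)
  }, logical(1))
  list(formula_agreement = mean(ok), n_lengths = length(lengths))
}
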