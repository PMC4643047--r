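test_that("synonymous site counts match the 9-neighbour enumeration oracle", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  S_pkg <- ervfossil:::ng_sites()
  expect_setequal(names(S_pkg), sense)
  for (codon in sense) {
    b <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0; valid <- 0
      for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
        nb <- b; nb[pos] <- alt
        nb <- paste(nb, collapse = "")
        if (gc[[nb]] == "*") next
        valid <- valid + 1
        if (gc[[nb]] == gc[[codon]]) syn <- syn + 1
      }
      if (valid > 0) s <- s + syn / valid
    }
    expect_equal(unname(S_pkg[codon]), s, info = codon)
  }
})

test_that("path-averaged differences avoid stop-codon intermediates", {
  D <- ervfossil:::ng_diffs()
  # single synonymous step
  expect_equal(D$sd["AAA", "AAG"], 1)
  expect_equal(D$nd["AAA", "AAG"], 0)
  # single nonsynonymous step
  expect_equal(D$sd["TTT", "TTA"], 0)
  expect_equal(D$nd["TTT", "TTA"], 1)
  # TGG <-> TAT: the path through TAG (stop) is excluded, leaving
  # TGG -> TGT -> TAT with two nonsynonymous steps
  expect_equal(D$sd["TGG", "TAT"], 0)
  expect_equal(D$nd["TGG", "TAT"], 2)
  # two-difference pair with both paths valid: average over orderings
  # GGG(G) <-> GAA(E): GGG->GAG(E)->GAA syn after nonsyn; GGG->GGA(G)->GAA
  expect_equal(D$sd["GGG", "GAA"], 1)
  expect_equal(D$nd["GGG", "GAA"], 1)
})

test_that("ng_dnds handles degenerate and one-sided alignments", {
  aln <- c(a = rep_str("AAAGGGCCCTTT", 10), b = rep_str("AAAGGGCCCTTT", 10))
  r <- ng_dnds(aln, n_boot = 0)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$verdict, "undefined")
  expect_true(is.na(omega_neutrality_test(aln, replicates = 100, seed = 1)))

  # synonymous-only difference: dN = 0, dS > 0
  r <- ng_dnds(c(a = rep_str("AAA", 40),
                 b = paste0("AAG", rep_str("AAA", 39))), n_boot = 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  # nonsynonymous-only difference: dS = 0, dN > 0, omega undefined
  r <- ng_dnds(c(a = rep_str("TTT", 40),
                 b = paste0("TTA", rep_str("TTT", 39))), n_boot = 0)
  expect_equal(r$dS, 0)
  expect_gt(r$dN, 0)
  expect_true(is.na(r$omega))

  # refuses alignments with fewer than 30 shared sense codons
  expect_error(ng_dnds(c(a = "AAAGGG", b = "AAAGGG")),
               class = "ervfossil_too_short")
  # gapped/stop columns do not count as shared
  aln <- c(a = paste0(rep_str("AAA", 29), "TAA"),
           b = paste0(rep_str("AAA", 29), "TAA"))
  expect_error(ng_dnds(aln), class = "ervfossil_too_short")
})

test_that("the neutrality bootstrap is deterministic given a seed", {
  set.seed(51)
  aln <- sim_codon_alignment(6, 100, omega = 0.4, branch_len = 0.1)
  p1 <- omega_neutrality_test(aln, replicates = 300, seed = 7)
  p2 <- omega_neutrality_test(aln, replicates = 300, seed = 7)
  expect_identical(p1, p2)
  expect_lt(p1, 0.05)  # strong purifying signal
  r <- ng_dnds(aln, n_boot = 300, seed = 7)
  expect_equal(r$verdict, "purifying")
})

test_that("exact Poisson intervals match their closed forms", {
  ci <- poisson_ci_exact(0, 1000)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], -log(0.025) / 1000, tolerance = 1e-7)
  ci <- poisson_ci_exact(5, 500)
  expect_equal(ci[["lower"]], 1.623486 / 500, tolerance = 1e-6)
  expect_equal(ci[["upper"]], 11.66833 / 500, tolerance = 1e-6)
  # the interval always contains the point estimate
  for (x in c(0, 1, 7, 100)) {
    ci <- poisson_ci_exact(x, 321)
    expect_true(ci[["lower"]] <= x / 321 && x / 321 <= ci[["upper"]])
  }
})

test_that("integrity counts planted stops and frameshifts exactly", {
  set.seed(52)
  sim <- sim_disrupted_domain(8, 200, stop_counts = c(0, 1, 2, 0, 1, 0, 0, 3),
                              fs_counts = c(0, 0, 1, 1, 0, 0, 1, 0))
  r <- integrity(sim$seqs, sim$consensus)
  expect_equal(r$n_stops, sum(sim$truth$n_stops))
  expect_equal(r$n_frameshifts, sum(sim$truth$n_frameshifts))
  expect_equal(r$freq, (r$n_stops + r$n_frameshifts) / r$n_codons)
  expect_true(r$ci95[["lower"]] <= r$freq && r$freq <= r$ci95[["upper"]])

  # a sequence identical to the consensus has zero events
  r0 <- integrity(sim$consensus, sim$consensus)
  expect_equal(r0$n_stops + r0$n_frameshifts, 0)
  expect_equal(r0$n_codons, 200)

  # in-frame (multiple of 3) deletions are not frameshifts
  s <- paste0(substr(sim$consensus, 1, 60), substr(sim$consensus, 67, 600))
  r3 <- integrity(s, sim$consensus)
  expect_equal(r3$n_frameshifts, 0)

  # a natural terminator on the consensus is not an event
  cons2 <- paste0(substr(sim$consensus, 1, 597), "TGA")
  r4 <- integrity(cons2, cons2)
  expect_equal(r4$n_stops, 0)
})

test_that("shared_breakpoints clusters deletions by breakpoint", {
  set.seed(53)
  # two distinct deletion lineages plus intact members
  fam <- sim_deletion_family(20, 8, region_len = 1200, del_start = 300,
                             del_end = 700,
                             second = list(n = 5, start = 800, end = 1100))
  bp <- shared_breakpoints(fam$seqs)
  expect_equal(nrow(bp), 2)
  expect_equal(sort(bp$n_sharing), c(5, 8))

  # all full length: nothing reported
  fam2 <- sim_deletion_family(10, 0, region_len = 800)
  expect_equal(nrow(shared_breakpoints(fam2$seqs)), 0)

  # breakpoints jittered within the 10 bp tolerance still cluster
  base <- rep_str("A", 1000)
  mk_del <- function(s, e) paste0(substr(base, 1, s),
                                  rep_str("-", e - s),
                                  substr(base, e + 1, 1000))
  seqs <- c(mk_del(300, 500), mk_del(308, 492), mk_del(295, 507))
  bp <- shared_breakpoints(seqs)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$n_sharing, 3)
})
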