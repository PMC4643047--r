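test_that("mask_cpg masks CG-context columns from either sequence", {
  m <- mask_cpg(list(seq_a = "ACGT", seq_b = "ACGT"))
  expect_identical(m$seq_a, "ANNT")
  expect_identical(m$seq_b, "ANNT")

  # decayed CpG (C->T) in one sequence still triggers the mask
  m <- mask_cpg(list(seq_a = "TG", seq_b = "CG"))
  expect_identical(m$seq_a, "NN")
  expect_identical(m$seq_b, "NN")

  # no CG anywhere: untouched
  m <- mask_cpg(list(seq_a = "ATTA", seq_b = "ATTA"))
  expect_identical(m$seq_a, "ATTA")

  # "first" mode ignores CpG private to the second sequence
  m <- mask_cpg(list(seq_a = "TG", seq_b = "CG"), mode = "first")
  expect_identical(m$seq_a, "TG")

  # CpG in the ungapped sequence spans an alignment gap
  m <- mask_cpg(list(seq_a = "AC-GT", seq_b = "ACTGT"))
  expect_identical(m$seq_a, "AN-NT")
  expect_identical(m$seq_b, "ANTNT")
})

test_that("k2p implements the closed form with usable-site bookkeeping", {
  same <- rep_str("ACTA", 30)
  r <- k2p(list(seq_a = same, seq_b = same))
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
  expect_equal(r$d, 0)
  expect_equal(r$usable_sites, 120)

  # P = 0.1, Q = 0.05 over 200 sites: d = -0.5 ln(0.75 sqrt(0.9))
  a <- rep_str("A", 200)
  b <- paste0(rep_str("G", 20), rep_str("C", 10), rep_str("A", 170))
  r <- k2p(list(seq_a = a, seq_b = b))
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75 * sqrt(0.9)))
  expect_equal(round(r$d, 4), 0.1702)

  # saturation: P = 0.5, Q = 0 makes the log argument zero
  a <- rep_str("A", 100)
  b <- paste0(rep_str("G", 50), rep_str("A", 50))
  r <- k2p(list(seq_a = a, seq_b = b))
  expect_true("saturated" %in% r$flags)
  expect_true(is.na(r$d))

  # gaps and N columns are skipped, low-confidence flagged under 50 sites
  r <- k2p(list(seq_a = "ACGTN-ACGT", seq_b = "ACGTAAAC-T"))
  expect_equal(r$usable_sites, 7)
  expect_true("low_confidence" %in% r$flags)
})

test_that("k2p matches independent column-count and ape oracles", {
  set.seed(13)
  for (i in 1:300) {
    L <- sample(60:200, 1)
    anc <- random_dna(L, runif(1, 0.3, 0.7))
    a <- mutate_seq(anc, 1, runif(1, 0, 0.2), ti_tv = runif(1, 0.5, 4))
    b <- mutate_seq(anc, 1, runif(1, 0, 0.2), ti_tv = runif(1, 0.5, 4))
    d_pkg <- k2p(list(seq_a = a, seq_b = b), min_sites = 1L)$d
    d_orc <- oracle_k2p(a, b)
    if (is.na(d_orc)) expect_true(is.na(d_pkg))
    else expect_equal(d_pkg, d_orc, tolerance = 1e-12)
  }
  # spot-check against ape on a subset
  for (i in 1:50) {
    anc <- random_dna(150, 0.5)
    a <- mutate_seq(anc, 1, 0.08)
    b <- mutate_seq(anc, 1, 0.08)
    d_pkg <- k2p(list(seq_a = a, seq_b = b), min_sites = 1L)$d
    m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    expect_equal(d_pkg, d_ape, tolerance = 1e-9)
  }
})

test_that("the two-LTR clock converts divergence to age", {
  expect_equal(ltr_age_years(0.054, 2.7e-9), 1.0e7)
  expect_equal(ltr_age_years(0.036, 1.8e-9), 1.0e7)
  expect_equal(ltr_age_years(0, 2.2e-9), 0)
})

test_that("date_provirus extracts, aligns and dates locus LTRs", {
  set.seed(21)
  ltr <- random_dna(600, 0.5)
  internal <- random_dna(5000, 0.5)
  host1 <- random_dna(1000, 0.5); host2 <- random_dna(1000, 0.5)
  genome <- c(chrA = paste0(host1, ltr, internal, ltr, host2))
  locus <- data.frame(locus_id = "p1", kind = "provirus", contig = "chrA",
                      start = 1000L, end = 1000L + 6200L, strand = "+",
                      ltr5_start = 1000L, ltr5_end = 1600L,
                      ltr3_start = 6600L, ltr3_end = 7200L,
                      stringsAsFactors = FALSE)
  r <- date_provirus(locus, genome, 2.7e-9)
  expect_equal(r$age_years, 0)

  # diverged LTRs on the minus strand: strand handling must not change d
  ltr2 <- mutate_seq(ltr, 5e6, 2.7e-9)
  elem <- paste0(ltr, internal, ltr2)
  gplus <- c(chrA = paste0(host1, elem, host2))
  gminus <- c(chrA = paste0(host1, revcomp(elem), host2))
  lplus <- locus
  lminus <- transform(locus, strand = "-",
                      ltr5_start = 6600L, ltr5_end = 7200L,
                      ltr3_start = 1000L, ltr3_end = 1600L)
  rp <- date_provirus(lplus, gplus, 2.7e-9)
  rm_ <- date_provirus(lminus, gminus, 2.7e-9)
  expect_gt(rp$age_years, 0)
  expect_equal(rp$d, rm_$d)
})

test_that("sliding windows follow the 300/50 bookkeeping", {
  s <- rep_str("ACTG", 250)   # 1000 columns
  prof <- sliding_identity(list(seq_a = s, seq_b = s))
  expect_equal(nrow(prof), 15)   # floor((1000-300)/50)+1
  expect_true(all(prof$identity == 1))
  expect_true(all(prof$k2p_identity == 1))
  expect_equal(prof$window_start, seq(0, 700, by = 50))

  # window-count formula across lengths
  set.seed(3)
  for (L in c(300, 301, 349, 350, 633, 1234)) {
    s <- random_dna(L, 0.5)
    prof <- sliding_identity(list(seq_a = s, seq_b = s))
    expect_equal(nrow(prof), floor((L - 300) / 50) + 1)
  }

  # a fully divergent block creates a local identity minimum
  set.seed(4)
  a <- random_dna(1000, 0.5)
  b <- paste0(substr(a, 1, 450), chartr("ACGT", "CATG", substr(a, 451, 550)),
              substr(a, 551, 1000))
  prof <- sliding_identity(list(seq_a = a, seq_b = b))
  # minimum at a window fully containing the divergent block (cols 450-549)
  expect_true(prof$window_start[which.min(prof$identity)] %in%
                seq(250, 450, 50))
  expect_equal(min(prof$identity), 200 / 300)

  # shorter than one window: single whole-alignment window with warning
  s <- random_dna(120, 0.5)
  expect_warning(prof <- sliding_identity(list(seq_a = s, seq_b = s)),
                 "shorter")
  expect_equal(nrow(prof), 1)
})
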