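test_that("solo-LTR completeness applies the 150/10 bp terminal rules", {
  len <- 600L
  # full-length hit
  expect_true(is_complete_solo_ltr(rm_hit(start = 0, end = 600), len))
  # missing exactly 150 bp at 5' fails the strict rule
  expect_false(is_complete_solo_ltr(
    rm_hit(start = 0, end = 450, cons_start = 151, cons_end = 600), len))
  # missing 149 bp passes
  expect_true(is_complete_solo_ltr(
    rm_hit(start = 0, end = 451, cons_start = 150, cons_end = 600), len))
  # missing 9 bp at 3' passes, 10 bp fails
  expect_true(is_complete_solo_ltr(
    rm_hit(start = 0, end = 591, cons_start = 1, cons_end = 591), len))
  expect_false(is_complete_solo_ltr(
    rm_hit(start = 0, end = 590, cons_start = 1, cons_end = 590), len))
  # inconsistent consensus length
  expect_error(is_complete_solo_ltr(rm_hit(start = 0, end = 700,
                                           cons_end = 700), len),
               "exceed")
})

test_that("pair_ltrs pairs LTRs across 3-10 kb gaps into proviruses", {
  # 5 kb gap -> one provirus spanning both LTRs
  hits <- rbind(rm_hit(start = 1000, end = 1600),
                rm_hit(start = 6600, end = 7200))
  loci <- pair_ltrs(hits, 600L)
  expect_equal(loci$kind, "provirus")
  expect_equal(loci$start, 1000)
  expect_equal(loci$end, 7200)
  expect_equal(loci$internal_gap_bp, 5000)

  # 2 kb gap -> no provirus, two complete solo LTRs
  hits <- rbind(rm_hit(start = 1000, end = 1600),
                rm_hit(start = 3600, end = 4200))
  loci <- pair_ltrs(hits, 600L)
  expect_equal(sum(loci$kind == "provirus"), 0)
  expect_equal(sum(loci$kind == "solo_ltr"), 2)

  # chain of three: leftmost pair forms the provirus, third is solo
  hits <- rbind(rm_hit(start = 0, end = 600),
                rm_hit(start = 5600, end = 6200),
                rm_hit(start = 11200, end = 11800))
  loci <- pair_ltrs(hits, 600L)
  expect_equal(sum(loci$kind == "provirus"), 1)
  expect_equal(sum(loci$kind == "solo_ltr"), 1)
  prov <- loci[loci$kind == "provirus", ]
  expect_equal(prov$start, 0)
  expect_equal(prov$end, 6200)
})

test_that("pair_ltrs never pairs across strands or contigs", {
  hits <- rbind(rm_hit(start = 1000, end = 1600, strand = "+"),
                rm_hit(start = 6600, end = 7200, strand = "-"))
  expect_equal(sum(pair_ltrs(hits, 600L)$kind == "provirus"), 0)

  hits <- rbind(rm_hit(contig = "c1", start = 1000, end = 1600),
                rm_hit(contig = "c2", start = 6600, end = 7200))
  expect_equal(sum(pair_ltrs(hits, 600L)$kind == "provirus"), 0)
})

test_that("minus-strand proviruses label the genomically rightmost LTR 5'", {
  hits <- rbind(rm_hit(start = 1000, end = 1600, strand = "-"),
                rm_hit(start = 6600, end = 7200, strand = "-"))
  loci <- pair_ltrs(hits, 600L)
  expect_equal(loci$kind, "provirus")
  expect_equal(loci$ltr5_start, 6600)
  expect_equal(loci$ltr3_start, 1000)
})

test_that("incomplete unpaired hits are dropped with a message", {
  hits <- rm_hit(start = 0, end = 440, cons_start = 161, cons_end = 600)
  expect_message(loci <- pair_ltrs(hits, 600L), "dropped")
  expect_equal(nrow(loci), 0)
})

test_that("fragmented hits are merged before pairing", {
  # one LTR split into two overlapping rows plus an intact partner
  hits <- rbind(rm_hit(start = 1000, end = 1400, cons_start = 1,
                       cons_end = 400, cons_left = 200),
                rm_hit(start = 1050, end = 1600, cons_start = 50,
                       cons_end = 600),
                rm_hit(start = 6600, end = 7200))
  m <- merge_ltr_hits(hits)
  expect_equal(nrow(m), 2)
  expect_equal(m$start[1], 1000)
  expect_equal(m$end[1], 1600)
  loci <- pair_ltrs(hits, 600L)
  expect_equal(sum(loci$kind == "provirus"), 1)
})

test_that("pairing count equals the exhaustive maximum on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    starts <- sort(sample.int(30000L, n))
    ends <- starts + 600L
    hits <- do.call(rbind, lapply(seq_len(n), function(k)
      rm_hit(start = starts[k], end = ends[k])))
    got <- sum(pair_ltrs(hits, 600L, merge = FALSE)$kind == "provirus")
    expect_equal(got, oracle_max_pairs(starts, ends),
                 info = paste("instance", i))
  }
})

test_that("filter_cst_hits applies the 80/80 rule and is monotone", {
  mk <- function(pident, len) data.frame(
    query_id = "q", contig = "s", sstart = 0L, send = len, strand = "+",
    pident = pident, aln_len = len, qstart = 0L, qend = len,
    evalue = 0, score = len, stringsAsFactors = FALSE)
  qlen <- 642L  # an RT-domain-sized query
  expect_equal(nrow(filter_cst_hits(mk(0.85, 642L), qlen)), 1)
  expect_equal(nrow(filter_cst_hits(mk(0.85, 321L), qlen)), 0)
  expect_equal(nrow(filter_cst_hits(mk(0.79, 642L), qlen)), 0)
  expect_equal(nrow(filter_cst_hits(mk(0.80, 514L), qlen)), 1)  # 0.8 * 642
  empty <- mk(0.9, 100L)[0, ]
  expect_equal(nrow(filter_cst_hits(empty, qlen)), 0)

  set.seed(7)
  hits <- do.call(rbind, lapply(1:50, function(i)
    mk(runif(1, 0.5, 1), sample.int(642L, 1))))
  base <- filter_cst_hits(hits, qlen)
  for (ident in c(0.85, 0.9)) for (frac in c(0.85, 0.9)) {
    tight <- filter_cst_hits(hits, qlen, min_identity = ident,
                             min_len_frac = frac)
    expect_true(all(rownames(tight) %in% rownames(base)))
  }
})

test_that("assign_family uses inclusive 80% alignment identity", {
  set.seed(11)
  member <- random_dna(300, 0.5)
  expect_true(assign_family(member, member))
  # every 3rd base substituted: ~67% identity
  ch <- strsplit(member, "")[[1]]
  idx <- seq(3, 300, by = 3)
  ch[idx] <- chartr("ACGT", "CATG", ch[idx])
  expect_false(assign_family(paste(ch, collapse = ""), member))
  # exactly 80% identity (60 of 300 substituted) is inclusive
  ch <- strsplit(member, "")[[1]]
  idx <- seq(5, 300, by = 5)
  ch[idx] <- chartr("ACGT", "CATG", ch[idx])
  expect_true(assign_family(paste(ch, collapse = ""), member))
  expect_error(assign_family(random_dna(49, 0.5), member), "50 bp")
})

test_that("copy_number totals proviruses plus solo LTRs", {
  mk_loci <- function(np, ns, fam = "F1") data.frame(
    locus_id = sprintf("l%04d", seq_len(np + ns)),
    kind = c(rep("provirus", np), rep("solo_ltr", ns)),
    contig = "c1", start = 0L, end = 1L, strand = "+", family_id = fam,
    stringsAsFactors = FALSE)
  # pangolin-like counts: 2 + 27 = 29
  tb <- copy_number(mk_loci(2, 27), "pangolin")
  expect_equal(tb$total, 29)
  # M. lucifugus-like counts: 204 + 1638 = 1842
  tb <- copy_number(mk_loci(204, 1638), "M_lucifugus")
  expect_equal(tb$proviruses, 204)
  expect_equal(tb$solo_ltrs, 1638)
  expect_equal(tb$total, 1842)
  # empty
  tb <- copy_number(mk_loci(1, 0)[0, ], "none")
  expect_equal(tb$total, 0)
})
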