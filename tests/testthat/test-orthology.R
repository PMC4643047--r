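test_that("make_probes extracts 200+200 bp probes with recorded junctions", {
  set.seed(31)
  g <- c(c1 = random_dna(10000, 0.5))
  locus <- data.frame(locus_id = "l1", kind = "provirus", contig = "c1",
                      start = 1000L, end = 8000L, strand = "+",
                      stringsAsFactors = FALSE)
  pr <- make_probes(locus, g)
  expect_identical(pr$p5$seq, substr(g[["c1"]], 801, 1200))
  expect_equal(pr$p5$junction_offset, 200)
  expect_identical(pr$p3$seq, substr(g[["c1"]], 7801, 8200))
  expect_equal(pr$p3$junction_offset, 200)
  expect_true(pr$p5$valid && pr$p3$valid)

  # near the contig edge: truncated with a warning, junction shifted
  locus$start <- 50L; locus$end <- 7050L
  expect_warning(pr <- make_probes(locus, g), "truncated")
  expect_identical(pr$p5$seq, substr(g[["c1"]], 1, 250))
  expect_equal(pr$p5$junction_offset, 50)

  # flank below 20 bp makes the side unusable
  locus$start <- 10L; locus$end <- 7010L
  expect_warning(pr <- make_probes(locus, g))
  expect_false(pr$p5$valid)

  # minus strand: probes in element orientation
  locus <- data.frame(locus_id = "l2", kind = "provirus", contig = "c1",
                      start = 1000L, end = 8000L, strand = "-",
                      stringsAsFactors = FALSE)
  pr <- make_probes(locus, g)
  expect_identical(pr$p5$seq, revcomp(substr(g[["c1"]], 7801, 8200)))
  expect_identical(pr$p3$seq, revcomp(substr(g[["c1"]], 801, 1200)))
})

test_that("search_probe reports exact coordinates on both strands", {
  set.seed(32)
  target <- c(t1 = random_dna(20000, 0.5))
  probe <- random_dna(400, 0.5)
  # plant probe[100..300) at target position 5000 (0-based), forward
  planted <- substr(probe, 101, 300)
  g <- target
  g[["t1"]] <- paste0(substr(g[["t1"]], 1, 5000), planted,
                      substr(g[["t1"]], 5201, 20000))
  idx <- kmer_index(g)
  h <- search_probe(probe, idx)
  top <- h[1, ]
  # the segment may extend a base or two past the planted boundary by
  # chance matches; the diagonal and coverage must be exact
  expect_equal(top$strand, "+")
  expect_equal(top$sstart - top$qstart, 4900)
  expect_equal(top$send - top$qend, 4900)
  expect_lte(top$qstart, 100); expect_gte(top$qstart, 96)
  expect_gte(top$qend, 300); expect_lte(top$qend, 304)
  expect_gte(top$pident, 0.98)

  # reverse-complement planting: minus-strand hit, probe coordinates kept
  g <- target
  g[["t1"]] <- paste0(substr(g[["t1"]], 1, 5000), revcomp(planted),
                      substr(g[["t1"]], 5201, 20000))
  h <- search_probe(probe, kmer_index(g))
  top <- h[1, ]
  expect_equal(top$strand, "-")
  expect_equal(top$sstart + top$qend, 5300)
  expect_equal(top$send + top$qstart, 5300)
  expect_lte(top$qstart, 100); expect_gte(top$qstart, 96)
  expect_gte(top$qend, 300); expect_lte(top$qend, 304)
  expect_gte(top$pident, 0.98)
})

mk_hit <- function(contig = "t1", sstart, send, strand = "+", qstart, qend,
                   pident = 1, score = NULL) {
  data.frame(query_id = "q", contig = contig, sstart = as.integer(sstart),
             send = as.integer(send), strand = strand, pident = pident,
             aln_len = send - sstart, qstart = as.integer(qstart),
             qend = as.integer(qend), evalue = NA_real_,
             score = if (is.null(score)) (send - sstart) * pident else score,
             stringsAsFactors = FALSE)
}

test_that("pair_flank_hits pairs junctions on one contig within 20 kb", {
  # 5p hit: probe [0,400) with junction 200 at target 1200
  h5 <- mk_hit(sstart = 1000, send = 1400, qstart = 0, qend = 400)
  h3 <- mk_hit(sstart = 7000, send = 7400, qstart = 0, qend = 400)
  p <- pair_flank_hits(h5, h3, 200, 200)
  expect_equal(p$j5, 1200)
  expect_equal(p$j3, 7200)
  expect_equal(p$gap, 6000)

  # different contigs never pair
  h3b <- mk_hit(contig = "t2", sstart = 7000, send = 7400,
                qstart = 0, qend = 400)
  expect_null(pair_flank_hits(h5, h3b, 200, 200))

  # beyond the span cap never pairs
  h3c <- mk_hit(sstart = 40000, send = 40400, qstart = 0, qend = 400)
  expect_null(pair_flank_hits(h5, h3c, 200, 200))

  # hits without host-flank coverage are rejected
  h5e <- mk_hit(sstart = 1200, send = 1400, qstart = 200, qend = 400)
  expect_null(pair_flank_hits(h5e, h3, 200, 200))
})

test_that("pair_flank_hits prefers flank-anchored, higher-scoring pairs", {
  h5 <- rbind(mk_hit(sstart = 1000, send = 1400, qstart = 0, qend = 400),
              mk_hit(sstart = 51000, send = 51210, qstart = 190,
                     qend = 400))
  h3 <- rbind(mk_hit(sstart = 7000, send = 7400, qstart = 0, qend = 400),
              mk_hit(sstart = 57000, send = 57400, qstart = 0, qend = 400))
  p <- pair_flank_hits(h5, h3, 200, 200)
  expect_equal(p$j5, 1200)  # fully flank-anchored pair wins
  # brute-force cross-check over all valid combinations
  best_flank <- -Inf
  for (i in 1:2) for (j in 1:2) {
    f5 <- max(0, min(h5$qend[i], 200) - h5$qstart[i])
    f3 <- max(0, h3$qend[j] - max(h3$qstart[j], 200))
    g <- (h3$sstart[j] + 200 - h3$qstart[j]) - (h5$sstart[i] + 200 - h5$qstart[i])
    if (f5 >= 20 && f3 >= 20 && g >= -50 && g <= 20000)
      best_flank <- max(best_flank, f5 + f3)
  }
  expect_equal(p$flank_score, best_flank)
})

test_that("call_state separates provirus, solo, empty and unresolved gaps", {
  set.seed(33)
  tg <- c(t1 = random_dna(30000, 0.5))
  locus <- data.frame(locus_id = "l1", kind = "provirus", contig = "c1",
                      start = 0L, end = 8200L, strand = "+",
                      stringsAsFactors = FALSE)
  mk_pair <- function(gap) {
    h5 <- mk_hit(sstart = 1000, send = 1400, qstart = 0, qend = 400)
    h3 <- mk_hit(sstart = 1200 + gap - 200, send = 1200 + gap + 200,
                 qstart = 0, qend = 400)
    pair_flank_hits(h5, h3, 200, 200)
  }
  expect_equal(call_state(mk_pair(8200), locus, 600, tg)$state,
               "present_provirus")
  expect_equal(call_state(mk_pair(600), locus, 600, tg)$state,
               "present_solo")
  expect_equal(call_state(mk_pair(660), locus, 600, tg)$state,
               "present_solo")   # within 20% of one LTR
  r <- call_state(mk_pair(-4), locus, 600, tg)
  expect_equal(r$state, "absent_empty")
  expect_identical(r$tsd_seq, substr(tg[["t1"]], 1197, 1200))
  expect_equal(call_state(mk_pair(2000), locus, 600, tg)$state,
               "unresolved")
  expect_equal(call_state(NULL, locus, 600, tg)$state, "unresolved")
})

test_that("orthology calls recover the truth on a small two-species pair", {
  cfg <- sim_config(seed = 34, genome_len = 3e5, n_ancestral = 3,
                    n_specific_a = 3, n_specific_b = 3,
                    solo_fraction = 0.3)
  sim <- sim_erv_genomes(cfg)
  tr <- sim$truth
  keep <- tr$kind_a != "absent"
  loci <- data.frame(locus_id = tr$locus_id[keep], kind = tr$kind_a[keep],
                     contig = "chrA", start = tr$start_a[keep],
                     end = tr$end_a[keep], strand = tr$strand[keep],
                     stringsAsFactors = FALSE)
  calls <- call_orthology(loci, sim$genome_a, sim$genome_b,
                          ltr_len = cfg$ltr_len, target_species = "B")
  want <- ifelse(tr$kind_b[match(calls$locus_id, tr$locus_id)] == "provirus",
                 "present_provirus",
                 ifelse(tr$kind_b[match(calls$locus_id, tr$locus_id)] ==
                          "solo_ltr", "present_solo", "absent_empty"))
  expect_identical(calls$state, want)
  ab <- calls$state == "absent_empty"
  expect_true(all(!is.na(calls$tsd_seq[ab])))
  expect_identical(calls$tsd_seq[ab],
                   tr$tsd[match(calls$locus_id[ab], tr$locus_id)])
})

test_that("orthology_matrix assigns loci by Dollo parsimony", {
  tree <- ape::read.tree(text = "((cat,tiger),dog);")
  mk_calls <- function(id, states) data.frame(
    locus_id = id, target_species = c("cat", "tiger", "dog"),
    state = states, stringsAsFactors = FALSE)
  calls <- rbind(
    mk_calls("l1", c("present_provirus", "present_solo", "absent_empty")),
    mk_calls("l2", c("present_provirus", "absent_empty", "absent_empty")),
    mk_calls("l3", c("present_provirus", "absent_empty", "present_solo")))
  res <- orthology_matrix(calls, tree)
  a <- res$assignments
  expect_equal(a$branch[a$locus_id == "l1"], "cat+tiger")
  expect_false(a$conflict[a$locus_id == "l1"])
  expect_equal(a$branch[a$locus_id == "l2"], "cat")
  # presence in cat and dog but absence in tiger requires a loss: conflict
  expect_true(a$conflict[a$locus_id == "l3"])
  expect_equal(sort(res$counts$branch), c("cat", "cat+tiger"))

  # single-species input degenerates to terminal assignments
  calls1 <- data.frame(locus_id = c("x", "y"), target_species = "cat",
                       state = "present_provirus", stringsAsFactors = FALSE)
  res1 <- orthology_matrix(calls1, tree)
  expect_true(all(res1$assignments$branch == "cat"))
})
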