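# Synthetic two-species genomes carrying ERV insertions with fully known
# ground truth. The generative model matches the assumptions under which the
# analyses are valid: a provirus integrates with two identical LTRs flanked
# by a 4 bp target-site duplication; each LTR then evolves independently
# under a Kimura two-parameter substitution process at the host neutral
# rate, with optional context-dependent CpG hypermutability (re-evaluated in
# 0.1 MY steps); ancestral insertions occupy the same host coordinate in
# both descendant genomes and continue evolving independently after the
# split; solo LTRs arise by recombination between the two LTRs; gene
# conversion overwrites a tract of one LTR with the other at a stated time.
# No indel process acts on LTRs apart from explicit conversion/deletion
# events.

TV1 <- c(A = "C", G = "C", C = "A", T = "A")
TV2 <- c(A = "T", G = "T", C = "G", T = "G")

#' Evolve a DNA sequence under a K2P substitution process
#'
#' With `cpg_multiplier = 1` substitutions are drawn directly from the K2P
#' transition probabilities for the full duration (exact). With a CpG
#' multiplier != 1 the process is discretised into `step_years` steps; at
#' each step sites currently in CpG context (the C or the G of a CG
#' dinucleotide) mutate at `cpg_multiplier` times the base rate, and the
#' context is re-evaluated after every step.
#'
#' @param seq DNA string.
#' @param years elapsed time.
#' @param rate neutral substitution rate (substitutions/site/year).
#' @param ti_tv transition/transversion ratio (default 2).
#' @param cpg_multiplier CpG rate multiplier (default 1).
#' @param step_years discretisation step for the context-dependent process
#'   (default 1e5 years).
#' @return the mutated DNA string.
#' @export
mutate_seq <- function(seq, years, rate, ti_tv = 2, cpg_multiplier = 1,
                       step_years = 1e5) {
  if (years <= 0) return(seq)
  x <- seq_chars(seq)
  n <- length(x)
  R <- ti_tv
  base <- is_base(x)
  if (cpg_multiplier == 1) {
    D <- rate * years
    at <- D * R / (R + 1)
    bt <- D / (2 * (R + 1))
    p_ti <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
    p_tv <- 0.5 - 0.5 * exp(-4 * bt)
    u <- runif(n)
    ti_i <- which(base & u < p_ti)
    tv_i <- which(base & u >= p_ti & u < p_ti + p_tv)
    old <- x
    x[ti_i] <- TI_PARTNER[old[ti_i]]
    if (length(tv_i)) {
      pick <- runif(length(tv_i)) < 0.5
      x[tv_i] <- ifelse(pick, TV1[old[tv_i]], TV2[old[tv_i]])
    }
  } else {
    nsteps <- max(1L, ceiling(years / step_years))
    dt <- years / nsteps
    for (s in seq_len(nsteps)) {
      isC <- x == "C"
      isG <- x == "G"
      cg <- isC & c(isG[-1], FALSE)
      ctx <- cg | c(FALSE, cg[-n])
      p <- rate * dt * ifelse(ctx, cpg_multiplier, 1)
      mut <- which(base & runif(n) < p)
      if (length(mut) == 0L) next
      old <- x[mut]
      is_ti <- runif(length(mut)) < R / (R + 1)
      pick <- runif(length(mut)) < 0.5
      x[mut] <- ifelse(is_ti, TI_PARTNER[old], ifelse(pick, TV1[old], TV2[old]))
    }
  }
  chars_seq(x)
}

# n insertion points in [margin, L - margin] with pairwise spacing >= s,
# via the order-statistics transform; errors when the genome cannot hold
# them.
spaced_positions <- function(n, L, s, margin) {
  span <- (L - 2 * margin) - (n - 1) * s
  if (span <= n) stop("impossible config: genome too short for ", n,
                      " insertions with ", s, " bp spacing")
  y <- sort(sample.int(span, n))
  as.integer(y + margin + (seq_len(n) - 1L) * s)
}

#' Simulation configuration for the two-species ERV genome generator
#'
#' Defaults are the conditions the analyses assume: 600 bp LTRs, 7 kb
#' internal region (inside the 3-10 kb provirus pairing window), 4 bp
#' target-site duplications, a vespertilionid-like neutral rate of 2.7e-9
#' substitutions/site/year, ti/tv ratio 2, and a 10 MY species split.
#' Insertion ages are drawn uniformly: ancestral insertions in
#' (split, 2 x split], lineage-specific ones in (0.05, 0.95) x split.
#' Minimum inter-insertion spacing exceeds the 10 kb pairing window so
#' that planted elements cannot be chained into spurious proviruses.
#'
#' @param seed RNG seed (all outputs are deterministic given the config).
#' @param genome_len host genome length in bp.
#' @param gc host and element GC content.
#' @param ltr_len,internal_len,tsd_len element geometry in bp.
#' @param rate_per_year,ti_tv,cpg_multiplier,step_years substitution process
#'   (see [mutate_seq()]).
#' @param split_time_years species A/B divergence time.
#' @param n_ancestral,n_specific_a,n_specific_b insertion counts by lineage.
#' @param solo_fraction per-lineage probability that an insertion is reduced
#'   to a solo LTR.
#' @param conversions data frame of gene-conversion events (`locus` index
#'   among ancestral insertions, `lineage` "A"/"B", `time_years`,
#'   `tract_fraction`), or NULL.
#' @param min_spacing,edge_margin placement constraints in bp.
#' @param family_id repeat-family label used in emitted hit tables.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_len = 1e6L, gc = 0.42,
                       ltr_len = 600L, internal_len = 7000L, tsd_len = 4L,
                       rate_per_year = 2.7e-9, ti_tv = 2,
                       cpg_multiplier = 1, step_years = 1e5,
                       split_time_years = 1e7,
                       n_ancestral = 10L, n_specific_a = 10L,
                       n_specific_b = 10L, solo_fraction = 0,
                       conversions = NULL,
                       min_spacing = 12000L, edge_margin = 500L,
                       family_id = "ERV1_LTR") {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rm_hit_row <- function(contig, start, end, strand, family_id, cons_len) {
  data.frame(score = 1000, contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand, family_id = family_id,
             cons_start = 1L, cons_end = as.integer(cons_len),
             cons_left = 0L, stringsAsFactors = FALSE)
}

# Overwrite a contiguous tract of `recipient` with the homologous tract of
# `donor` (equal lengths), covering `fraction` of the sequence at a random
# offset.
convert_tract <- function(recipient, donor, fraction) {
  n <- nchar(recipient)
  len <- max(1L, round(fraction * n))
  start <- if (len >= n) 1L else sample.int(n - len + 1L, 1L)
  paste0(substr(recipient, 1, start - 1L),
         substr(donor, start, start + len - 1L),
         substr(recipient, start + len, n))
}

#' Simulate two species genomes with planted ERV insertions
#'
#' Generates a shared ancestral host genome, plants ancestral (pre-split)
#' and lineage-specific insertions with target-site duplications, evolves
#' every LTR and internal region along its true history, applies solo-LTR
#' reduction and gene-conversion events, and emits per-species genomes,
#' RepeatMasker-dialect hit tables (LTR hits) and a ground-truth ledger.
#'
#' @param config a [sim_config()].
#' @return a list with `genome_a`, `genome_b` (named character vectors, one
#'   contig `"chrA"` each), `rm_a`, `rm_b` (repeat-hit data frames), `truth`
#'   (data frame: `locus_id`, `lineage`, `age_years`, `strand`, `pos_anc`
#'   -- 0-based insertion point on the ancestral host --, `tsd`, per-genome
#'   `kind_a`/`start_a`/`end_a` and `kind_b`/`start_b`/`end_b` with
#'   `kind = "absent"` where not inserted, `converted_a`, `converted_b`) and
#'   `config`.
#' @export
sim_erv_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  host <- random_dna(cfg$genome_len, cfg$gc)
  ltr_cons <- random_dna(cfg$ltr_len, cfg$gc)
  int_cons <- random_dna(cfg$internal_len, cfg$gc)
  n_total <- cfg$n_ancestral + cfg$n_specific_a + cfg$n_specific_b
  lineage <- c(rep("ancestral", cfg$n_ancestral),
               rep("A", cfg$n_specific_a), rep("B", cfg$n_specific_b))
  split <- cfg$split_time_years
  age <- c(runif(cfg$n_ancestral, split, 2 * split),
           runif(cfg$n_specific_a + cfg$n_specific_b,
                 0.05 * split, 0.95 * split))
  pos <- spaced_positions(n_total, cfg$genome_len, cfg$min_spacing,
                          cfg$edge_margin)
  ord <- sample.int(n_total)          # decouple lineage from position order
  lineage <- lineage[ord]; age <- age[ord]
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  mut <- function(s, yrs) mutate_seq(s, yrs, cfg$rate_per_year, cfg$ti_tv,
                                     cfg$cpg_multiplier, cfg$step_years)
  conv <- cfg$conversions
  anc_idx <- which(lineage == "ancestral")
  loci <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    tsd <- substr(host, pos[i] + 1L, pos[i] + cfg$tsd_len)
    rec <- list(lineage = lineage[i], age = age[i], strand = strand[i],
                pos = pos[i], tsd = tsd, converted = c(A = FALSE, B = FALSE),
                kind = c(A = "absent", B = "absent"), seqs = list())
    present_in <- switch(lineage[i], ancestral = c("A", "B"),
                         A = "A", B = "B")
    anc_dur <- if (lineage[i] == "ancestral") age[i] - split else 0
    l5_0 <- if (anc_dur > 0) mut(ltr_cons, anc_dur) else ltr_cons
    l3_0 <- if (anc_dur > 0) mut(ltr_cons, anc_dur) else ltr_cons
    in_0 <- if (anc_dur > 0) mut(int_cons, anc_dur) else int_cons
    for (X in present_in) {
      dur <- if (lineage[i] == "ancestral") split else age[i]
      cv <- NULL
      if (!is.null(conv) && lineage[i] == "ancestral") {
        k <- which(conv$locus == match(i, anc_idx) & conv$lineage == X)
        if (length(k) == 1L) cv <- conv[k, ]
      }
      if (is.null(cv)) {
        l5 <- mut(l5_0, dur); l3 <- mut(l3_0, dur)
      } else {
        tc <- cv$time_years
        l5 <- mut(l5_0, dur - tc); l3 <- mut(l3_0, dur - tc)
        l5 <- convert_tract(l5, l3, cv$tract_fraction)
        l5 <- mut(l5, tc); l3 <- mut(l3, tc)
        rec$converted[X] <- TRUE
      }
      int <- mut(in_0, dur)
      solo <- runif(1) < cfg$solo_fraction
      rec$kind[X] <- if (solo) "solo_ltr" else "provirus"
      rec$seqs[[X]] <- if (solo) list(elem = l5)
                       else list(elem = paste0(l5, int, l3))
    }
    loci[[i]] <- rec
  }
  assemble <- function(X) {
    segs <- character(0)
    rm_rows <- list()
    coords <- matrix(NA_integer_, n_total, 2)
    prev <- 0L   # 0-based position consumed on the host
    offset <- 0L
    for (i in seq_len(n_total)) {
      rec <- loci[[i]]
      if (rec$kind[X] == "absent") next
      p <- rec$pos
      segs <- c(segs, subseq0(host, prev, p + cfg$tsd_len))
      elem <- rec$seqs[[X]]$elem
      if (rec$strand == "-") elem <- revcomp(elem)
      len <- nchar(elem)
      start0 <- p + cfg$tsd_len + offset
      segs <- c(segs, elem, rec$tsd)
      coords[i, ] <- c(start0, start0 + len)
      if (rec$kind[X] == "provirus") {
        rm_rows[[length(rm_rows) + 1L]] <- rbind(
          rm_hit_row("chrA", start0, start0 + cfg$ltr_len, rec$strand,
                     cfg$family_id, cfg$ltr_len),
          rm_hit_row("chrA", start0 + len - cfg$ltr_len, start0 + len,
                     rec$strand, cfg$family_id, cfg$ltr_len))
      } else {
        rm_rows[[length(rm_rows) + 1L]] <- rm_hit_row(
          "chrA", start0, start0 + len, rec$strand, cfg$family_id,
          cfg$ltr_len)
      }
      offset <- offset + len + cfg$tsd_len
      prev <- p + cfg$tsd_len
    }
    segs <- c(segs, subseq0(host, prev, cfg$genome_len))
    genome <- setNames(paste(segs, collapse = ""), "chrA")
    rm <- if (length(rm_rows)) do.call(rbind, rm_rows) else empty_rm_hits()
    list(genome = genome, rm = rm, coords = coords)
  }
  ga <- assemble("A")
  gb <- assemble("B")
  truth <- data.frame(
    locus_id = sprintf("sim_%03d", seq_len(n_total)),
    lineage = lineage, age_years = age, strand = strand,
    pos_anc = pos, tsd = vapply(loci, `[[`, character(1), "tsd"),
    kind_a = vapply(loci, function(r) r$kind[["A"]], character(1)),
    start_a = ga$coords[, 1], end_a = ga$coords[, 2],
    kind_b = vapply(loci, function(r) r$kind[["B"]], character(1)),
    start_b = gb$coords[, 1], end_b = gb$coords[, 2],
    converted_a = vapply(loci, function(r) r$converted[["A"]], logical(1)),
    converted_b = vapply(loci, function(r) r$converted[["B"]], logical(1)),
    stringsAsFactors = FALSE
  )
  list(genome_a = ga$genome, genome_b = gb$genome,
       rm_a = ga$rm, rm_b = gb$rm, truth = truth, config = cfg)
}

# empty repeat-hit frame (when a lineage has no insertions)
empty_rm_hits <- function() {
  data.frame(score = numeric(0), contig = character(0), start = integer(0),
             end = integer(0), strand = character(0), family_id = character(0),
             cons_start = integer(0), cons_end = integer(0),
             cons_left = integer(0), stringsAsFactors = FALSE)
}

#' Simulate a single annotated genome of proviruses and solo LTRs
#'
#' Plants `n_provirus` proviruses (internal length drawn uniformly within
#' the pairing window) and `n_solo` solo LTRs of random age on one host
#' contig and emits the genome, the LTR hit table and the truth ledger.
#' Elements are spaced by more than the pairing window so no spurious
#' cross-element provirus is constructible.
#'
#' @param n_provirus,n_solo element counts.
#' @param config a [sim_config()]; `internal_len` is re-drawn per provirus
#'   in \[3000, 10000\] minus LTRs unless `fixed_internal = TRUE`.
#' @param fixed_internal use `config$internal_len` for every provirus.
#' @return a list with `genome`, `rm` (hit table), `truth` (data frame with
#'   `locus_id`, `kind`, `age_years`, `strand`, `start`, `end`,
#'   `internal_len`) and `config`.
#' @export
sim_annotation_genome <- function(n_provirus, n_solo, config = sim_config(),
                                  fixed_internal = FALSE) {
  cfg <- config
  set.seed(cfg$seed)
  n_total <- n_provirus + n_solo
  host <- random_dna(cfg$genome_len, cfg$gc)
  ltr_cons <- random_dna(cfg$ltr_len, cfg$gc)
  kind <- sample(c(rep("provirus", n_provirus), rep("solo_ltr", n_solo)))
  pos <- spaced_positions(n_total, cfg$genome_len, cfg$min_spacing,
                          cfg$edge_margin)
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  age <- runif(n_total, 5e5, 1e7)
  mut <- function(s, yrs) mutate_seq(s, yrs, cfg$rate_per_year, cfg$ti_tv,
                                     cfg$cpg_multiplier, cfg$step_years)
  segs <- character(0); rm_rows <- list()
  prev <- 0L; offset <- 0L
  truth <- list()
  for (i in seq_len(n_total)) {
    p <- pos[i]
    tsd <- substr(host, p + 1L, p + cfg$tsd_len)
    int_len <- if (kind[i] == "provirus") {
      if (fixed_internal) cfg$internal_len
      else sample(3000:10000, 1L)
    } else 0L
    if (kind[i] == "provirus") {
      elem <- paste0(mut(ltr_cons, age[i]), random_dna(int_len, cfg$gc),
                     mut(ltr_cons, age[i]))
    } else {
      elem <- mut(ltr_cons, age[i])
    }
    if (strand[i] == "-") elem <- revcomp(elem)
    len <- nchar(elem)
    segs <- c(segs, subseq0(host, prev, p + cfg$tsd_len), elem, tsd)
    start0 <- p + cfg$tsd_len + offset
    if (kind[i] == "provirus") {
      rm_rows[[length(rm_rows) + 1L]] <- rbind(
        rm_hit_row("chrA", start0, start0 + cfg$ltr_len, strand[i],
                   cfg$family_id, cfg$ltr_len),
        rm_hit_row("chrA", start0 + len - cfg$ltr_len, start0 + len,
                   strand[i], cfg$family_id, cfg$ltr_len))
    } else {
      rm_rows[[length(rm_rows) + 1L]] <- rm_hit_row(
        "chrA", start0, start0 + len, strand[i], cfg$family_id, cfg$ltr_len)
    }
    truth[[i]] <- data.frame(
      locus_id = sprintf("true_%03d", i), kind = kind[i],
      age_years = age[i], strand = strand[i], start = start0,
      end = start0 + len, internal_len = int_len, stringsAsFactors = FALSE)
    offset <- offset + len + cfg$tsd_len
    prev <- p + cfg$tsd_len
  }
  segs <- c(segs, subseq0(host, prev, cfg$genome_len))
  list(genome = setNames(paste(segs, collapse = ""), "chrA"),
       rm = do.call(rbind, rm_rows), truth = do.call(rbind, truth),
       config = cfg)
}

#' Simulate LTR pairs of known insertion age
#'
#' Each pair starts from an independent random ancestor LTR (identical
#' copies at insertion) and the two copies evolve independently for
#' `age_years` under the configured K2P/CpG process.
#'
#' @param n number of proviruses.
#' @param age_years true insertion age.
#' @param ltr_len LTR length in bp (default 1000).
#' @param rate,ti_tv,cpg_multiplier,step_years,gc process parameters.
#' @return a list of `n` lists with elements `ltr5`, `ltr3`.
#' @export
sim_ltr_pairs <- function(n, age_years, ltr_len = 1000L, rate = 2.7e-9,
                          ti_tv = 2, cpg_multiplier = 1, step_years = 1e5,
                          gc = 0.5) {
  lapply(seq_len(n), function(i) {
    anc <- random_dna(ltr_len, gc)
    list(ltr5 = mutate_seq(anc, age_years, rate, ti_tv, cpg_multiplier,
                           step_years),
         ltr3 = mutate_seq(anc, age_years, rate, ti_tv, cpg_multiplier,
                           step_years))
  })
}

#' Simulate LTR quartets with and without post-speciation gene conversion
#'
#' Emulates an orthologous provirus shared by two species: insertion at
#' `insertion_years`, speciation at `split_years`, all four LTR lineages
#' evolving neutrally; in converted cases a tract of the 5' LTR is
#' overwritten by the 3' LTR in both lineages at an independent random time
#' in `conv_window`, with tract fraction drawn from `tract_range`. The
#' outgroup is a non-orthologous LTR of the same family.
#'
#' @param n number of quartets.
#' @param p_converted fraction of quartets carrying conversion.
#' @param ltr_len LTR length in bp (default 600).
#' @param rate substitution rate per year.
#' @param ti_tv transition/transversion ratio.
#' @param split_years,insertion_years,outgroup_years event times.
#' @param conv_window two-element range of conversion times (years ago).
#' @param tract_range two-element range of converted tract fractions.
#' @param gc GC content.
#' @return a list with `cases` (quartet-case lists for
#'   [conversion_screen()]) and `truth` (logical vector: converted).
#' @export
sim_quartets <- function(n, p_converted = 0.5, ltr_len = 600L,
                         rate = 2.7e-9, ti_tv = 2,
                         split_years = 1e7, insertion_years = 1.4e7,
                         outgroup_years = 2.5e7,
                         conv_window = c(1e6, 5e6),
                         tract_range = c(0.8, 1), gc = 0.5) {
  converted <- runif(n) < p_converted
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- random_dna(ltr_len, gc)
    pre <- insertion_years - split_years
    l5p <- mutate_seq(anc, pre, rate, ti_tv)
    l3p <- mutate_seq(anc, pre, rate, ti_tv)
    evolve_lineage <- function() {
      if (converted[i]) {
        tc <- runif(1, conv_window[1], conv_window[2])
        f <- runif(1, tract_range[1], tract_range[2])
        l5 <- mutate_seq(l5p, split_years - tc, rate, ti_tv)
        l3 <- mutate_seq(l3p, split_years - tc, rate, ti_tv)
        l5 <- convert_tract(l5, l3, f)
        list(l5 = mutate_seq(l5, tc, rate, ti_tv),
             l3 = mutate_seq(l3, tc, rate, ti_tv))
      } else {
        list(l5 = mutate_seq(l5p, split_years, rate, ti_tv),
             l3 = mutate_seq(l3p, split_years, rate, ti_tv))
      }
    }
    A <- evolve_lineage(); B <- evolve_lineage()
    cases[[i]] <- list(locus_id = sprintf("q_%03d", i),
                       ltr5_a = A$l5, ltr3_a = A$l3,
                       ltr5_b = B$l5, ltr3_b = B$l3,
                       outgroup = mutate_seq(anc, 2 * outgroup_years, rate,
                                             ti_tv))
  }
  list(cases = cases, truth = converted)
}

#' Simulate a codon alignment under a simple codon model
#'
#' A star tree of `n_seq` taxa: each tip evolves independently from a random
#' ancestral sense-codon sequence for `branch_len` expected substitutions
#' per site (under neutrality). Single-base codon changes occur at rate
#' proportional to `kappa` for transitions and `omega` for nonsynonymous
#' changes; changes creating stop codons are forbidden. `kappa = 1`
#' (default) matches the no-transition-bias assumption of Nei-Gojobori site
#' counting so that omega recovery can be assessed without the well-known
#' counting bias under transition bias.
#'
#' @param n_seq number of sequences.
#' @param n_codons alignment length in codons.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param branch_len tip branch length (expected neutral substitutions per
#'   site).
#' @param kappa transition/transversion rate ratio (default 1).
#' @return a named character vector of `n_seq` coding sequences.
#' @export
sim_codon_alignment <- function(n_seq = 10L, n_codons = 300L, omega = 1,
                                branch_len = 0.1, kappa = 1) {
  anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  evolve_codon <- function(codon, t) {
    repeat {
      nbs <- codon_neighbours(codon)
      ok <- !(nbs %in% STOP_CODONS)
      aa <- translate_codon(codon)
      rates <- numeric(length(nbs))
      for (j in which(ok)) {
        r <- 1
        cpos <- which(seq_chars(codon) != seq_chars(nbs[j]))
        b1 <- substr(codon, cpos, cpos); b2 <- substr(nbs[j], cpos, cpos)
        if (TI_PARTNER[[b1]] == b2) r <- r * kappa
        if (translate_codon(nbs[j]) != aa) r <- r * omega
        rates[j] <- r
      }
      total <- sum(rates) / 3   # per-position neutral rate 1 when kappa=omega=1
      if (total <= 0) return(codon)
      w <- rexp(1, total)
      if (w > t) return(codon)
      t <- t - w
      codon <- sample(nbs, 1, prob = rates)
    }
  }
  seqs <- vapply(seq_len(n_seq), function(s)
    paste(vapply(anc, evolve_codon, character(1), t = branch_len),
          collapse = ""), character(1))
  setNames(seqs, sprintf("seq%02d", seq_len(n_seq)))
}

#' Simulate a family with shared envelope-deletion breakpoints
#'
#' Members diverge slightly from a common reference; `n_del` of them carry
#' one identical internal deletion (optionally a second deletion lineage
#' with distinct breakpoints), mirroring amplification from a
#' deletion-bearing progenitor.
#'
#' @param n family size.
#' @param n_del members carrying the primary deletion.
#' @param region_len reference length in bp.
#' @param del_start,del_end 0-based deletion breakpoints.
#' @param divergence expected substitutions/site from the reference.
#' @param second optional list(n, start, end) describing a second deletion
#'   lineage.
#' @param gc GC content.
#' @return a list with `ref` and `seqs` (aligned to `ref` coordinates) and
#'   `truth` (per-member deletion label).
#' @export
sim_deletion_family <- function(n = 43L, n_del = 29L, region_len = 1800L,
                                del_start = 600L, del_end = 1500L,
                                divergence = 0.02, second = NULL, gc = 0.5) {
  ref <- random_dna(region_len, gc)
  n2 <- if (is.null(second)) 0L else second$n
  label <- sample(c(rep("del1", n_del), rep("del2", n2),
                    rep("intact", n - n_del - n2)))
  seqs <- vapply(seq_len(n), function(i) {
    s <- mutate_seq(ref, 1, divergence, ti_tv = 2)
    if (label[i] == "del1") {
      substr(s, del_start + 1L, del_end) <-
        chars_seq(rep("-", del_end - del_start))
    } else if (label[i] == "del2") {
      substr(s, second$start + 1L, second$end) <-
        chars_seq(rep("-", second$end - second$start))
    }
    s
  }, character(1))
  list(ref = ref, seqs = seqs, truth = label)
}

#' Simulate domain sequences with planted ORF disruptions
#'
#' Starts from an intact sense-codon consensus; each member carries a stated
#' number of planted stop codons (first half of the domain) and at most one
#' 1-bp frameshift deletion (second half), so the planted event count is
#' exactly recoverable.
#'
#' @param n_seq number of members.
#' @param n_codons domain length in codons.
#' @param stop_counts integer vector (length `n_seq`) of stops to plant.
#' @param fs_counts integer vector of frameshifts (0 or 1) to plant.
#' @return a list with `consensus`, `seqs` and `truth` (per-member planted
#'   counts).
#' @export
sim_disrupted_domain <- function(n_seq = 10L, n_codons = 200L,
                                 stop_counts = rep(0L, n_seq),
                                 fs_counts = rep(0L, n_seq)) {
  stopifnot(length(stop_counts) == n_seq, length(fs_counts) == n_seq,
            all(fs_counts %in% 0:1))
  cons <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
  half <- floor(n_codons / 2)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- cons
    if (stop_counts[i] > 0L) {
      at <- sample(seq_len(half), stop_counts[i])
      for (ci in at)
        substr(s, 3 * ci - 2, 3 * ci) <- "TAA"
    }
    if (fs_counts[i] == 1L) {
      ci <- sample((half + 2L):n_codons, 1L)
      s <- paste0(substr(s, 1, 3 * ci - 3), substr(s, 3 * ci - 1, nchar(s)))
    }
    s
  }, character(1))
  list(consensus = cons, seqs = seqs,
       truth = data.frame(n_stops = stop_counts, n_frameshifts = fs_counts))
}

#' Degrade a repeat-hit table to exercise merge/completeness logic
#'
#' Random hit fragmentation (one hit split into two rows at an internal
#' consensus point) and terminal truncation (consensus bp lost at the 5'
#' and/or 3' consensus end, with the genomic interval shortened to match).
#' Deterministic given `seed`.
#'
#' @param hits repeat-hit data frame.
#' @param frag_prob per-hit fragmentation probability.
#' @param end_loss list with numeric vectors `p5` and `p3` to sample losses
#'   from (default `list(p5 = 0, p3 = 0)`).
#' @param seed optional RNG seed.
#' @return the degraded hit table.
#' @export
degrade_rm_out <- function(hits, frag_prob = 0,
                           end_loss = list(p5 = 0, p3 = 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    l5 <- if (length(end_loss$p5) == 1L) end_loss$p5
          else sample(end_loss$p5, 1L)
    l3 <- if (length(end_loss$p3) == 1L) end_loss$p3
          else sample(end_loss$p3, 1L)
    cons_len <- h$cons_end - h$cons_start + 1L
    if (l5 + l3 < cons_len - 50L) {
      h$cons_start <- h$cons_start + as.integer(l5)
      h$cons_end <- h$cons_end - as.integer(l3)
      h$cons_left <- h$cons_left + as.integer(l3)
      if (h$strand == "+") {
        h$start <- h$start + as.integer(l5); h$end <- h$end - as.integer(l3)
      } else {
        h$start <- h$start + as.integer(l3); h$end <- h$end - as.integer(l5)
      }
    }
    if (runif(1) < frag_prob && (h$cons_end - h$cons_start) > 100L) {
      m <- sample((h$cons_start + 50L):(h$cons_end - 50L), 1L)
      left_len <- m - h$cons_start + 1L
      h1 <- h; h2 <- h
      if (h$strand == "+") {
        h1$end <- h1$start + left_len
        h1$cons_end <- m
        h1$cons_left <- h$cons_left + (h$cons_end - m)
        h2$start <- h1$end
        h2$cons_start <- m + 1L
      } else {
        h1$start <- h1$end - left_len
        h1$cons_end <- m
        h1$cons_left <- h$cons_left + (h$cons_end - m)
        h2$end <- h1$start
        h2$cons_start <- m + 1L
      }
      out[[length(out) + 1L]] <- h1
      out[[length(out) + 1L]] <- h2
    } else {
      out[[length(out) + 1L]] <- h
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
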