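# Orthologous-insertion calling. For each donor-genome ERV locus the two
# element termini plus host flanks are extracted as probes, searched against
# a target genome, the 5' and 3' hits are paired, and the distance between
# the element/host junctions in the target is interpreted: a full-element
# gap means an orthologous provirus, an LTR-sized gap an orthologous solo
# LTR, and contiguous flanks (overlapping by the target-site duplication) a
# pre-insertion empty site.

#' Extract 5' and 3' flank probes for a locus
#'
#' Each probe is up to 200 bp of element terminus plus up to 200 bp of host
#' flank, emitted in element orientation (minus-strand loci are
#' reverse-complemented). The element/host junction offset within the probe
#' is recorded. Probes are truncated with a warning when the locus lies
#' within 200 bp of a contig edge; a flank shorter than `min_flank` makes
#' that side unusable (`valid = FALSE`), which propagates to an unresolved
#' call.
#'
#' @param locus one row of an ERV locus data frame.
#' @param genome named character vector of contig sequences (donor genome).
#' @param flank,elem host-flank and element-terminus lengths in bp
#'   (default 200 each).
#' @param min_flank minimum usable flank length in bp (default 20).
#' @return a list with elements `p5` and `p3`, each a list with `side`,
#'   `seq`, `junction_offset` (0-based position of the element/host boundary
#'   within the probe) and `valid`.
#' @export
make_probes <- function(locus, genome, flank = 200L, elem = 200L,
                        min_flank = 20L) {
  seq <- genome[[locus$contig]]
  L <- nchar(seq)
  s <- locus$start; e <- locus$end
  if (s < flank || L - e < flank)
    warning("locus ", locus$locus_id, " within ", flank,
            " bp of a contig edge: probe truncated")
  if (locus$strand == "+") {
    up_len <- min(flank, s)
    p5_seq <- subseq0(seq, s - up_len, min(e, s + elem))
    p5 <- list(side = "5p", seq = p5_seq, junction_offset = up_len,
               valid = up_len >= min_flank)
    dn_len <- min(flank, L - e)
    p3_seq <- subseq0(seq, max(s, e - elem), e + dn_len)
    p3 <- list(side = "3p", seq = p3_seq,
               junction_offset = nchar(p3_seq) - dn_len,
               valid = dn_len >= min_flank)
  } else {
    # element 5' terminus is at the genomic right edge
    up_len <- min(flank, L - e)
    p5_seq <- revcomp(subseq0(seq, max(s, e - elem), e + up_len))
    p5 <- list(side = "5p", seq = p5_seq, junction_offset = up_len,
               valid = up_len >= min_flank)
    dn_len <- min(flank, s)
    p3_seq <- revcomp(subseq0(seq, s - dn_len, min(e, s + elem)))
    p3 <- list(side = "3p", seq = p3_seq,
               junction_offset = nchar(p3_seq) - dn_len,
               valid = dn_len >= min_flank)
  }
  list(p5 = p5, p3 = p3)
}

# Map a probe-orientation position to a target forward-strand position for
# an ungapped hit. pos is 0-based within the probe; returns a 0-based target
# position (extrapolated linearly if pos falls outside the hit's segment).
map_to_target <- function(hit, pos) {
  if (hit$strand == "+") hit$sstart + (pos - hit$qstart)
  else hit$send - (pos - hit$qstart)
}

#' Pair 5' and 3' flank-probe hits in a target genome
#'
#' Candidate pairs must lie on the same target contig and strand with the 5'
#' junction upstream of the 3' junction in element orientation and a signed
#' junction gap between `-50` bp (junction overlap, as at an empty site with
#' a target-site duplication) and `max_span`. Because element termini are
#' repetitive while host flanks are locus-specific, each hit must cover at
#' least `min_flank_cov` bp of the host side of its junction, and pairs are
#' ranked by flank-side coverage score (summed segment score as tie-break);
#' this keeps hits to unrelated element copies from outcompeting the true
#' orthologous site.
#'
#' @param hits5,hits3 search-hit data frames for the 5' and 3' probes of one
#'   locus (internal backend or BLAST tabular).
#' @param junction5,junction3 0-based element/host junction offsets within
#'   the respective probes (see [make_probes()]).
#' @param max_span maximal junction separation in bp (default 20000).
#' @param min_flank_cov minimum host-flank coverage per hit in bp
#'   (default 20).
#' @return `NULL` if no pair qualifies, else a list with `hit5`, `hit3`,
#'   `gap` (signed junction distance in element orientation), `contig`,
#'   `j5`, `j3` (target junction positions), `flank_score` and `score`.
#' @export
pair_flank_hits <- function(hits5, hits3, junction5, junction3,
                            max_span = 20000L, min_flank_cov = 20L) {
  if (nrow(hits5) == 0L || nrow(hits3) == 0L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(hits5))) {
    h5 <- hits5[i, ]
    j5 <- map_to_target(h5, junction5)
    # host flank of the 5' probe lies before its junction
    f5 <- max(0L, min(h5$qend, junction5) - h5$qstart)
    if (f5 < min_flank_cov) next
    for (j in seq_len(nrow(hits3))) {
      h3 <- hits3[j, ]
      if (h3$contig != h5$contig || h3$strand != h5$strand) next
      f3 <- max(0L, h3$qend - max(h3$qstart, junction3))
      if (f3 < min_flank_cov) next
      j3 <- map_to_target(h3, junction3)
      g <- if (h5$strand == "+") j3 - j5 else j5 - j3
      if (g < -50L || g > max_span) next
      fsc <- f5 * h5$pident + f3 * h3$pident
      sc <- h5$score + h3$score
      if (is.null(best) || fsc > best$flank_score ||
          (fsc == best$flank_score && sc > best$score))
        best <- list(hit5 = h5, hit3 = h3, gap = g, contig = h5$contig,
                     j5 = j5, j3 = j3, flank_score = fsc, score = sc)
    }
  }
  best
}

#' Interpret a paired-flank hit as a presence/absence state
#'
#' With signed junction gap g: `g >= 0.8 *` element length (and above the
#' solo-LTR band, `g > 1.2 * ltr_len`) means an orthologous provirus;
#' `|g - ltr_len| <= 0.2 * ltr_len` an orthologous solo LTR; `|g| <= 25` bp a pre-insertion empty site (the flanks are
#' contiguous up to the target-site duplication, which is recorded when the
#' junctions overlap by 2-10 bp); anything else, or no pair, is unresolved.
#'
#' @param pair result of [pair_flank_hits()], or `NULL`.
#' @param locus the donor locus row (for the element extent length).
#' @param ltr_len LTR length in bp.
#' @param target_genome named character vector of target contig sequences
#'   (used to read the TSD at an empty site).
#' @param target_species species label copied into the call.
#' @return a one-row data frame with columns `locus_id`, `target_species`,
#'   `state`, `target_contig`, `target_start`, `target_end`, `tsd_seq`.
#' @export
call_state <- function(pair, locus, ltr_len, target_genome,
                       target_species = "target") {
  res <- data.frame(
    locus_id = locus$locus_id, target_species = target_species,
    state = "unresolved", target_contig = NA_character_,
    target_start = NA_integer_, target_end = NA_integer_,
    tsd_seq = NA_character_, stringsAsFactors = FALSE
  )
  if (is.null(pair)) return(res)
  g <- pair$gap
  elem_len <- locus$end - locus$start
  lo <- min(pair$j5, pair$j3); hi <- max(pair$j5, pair$j3)
  res$target_contig <- pair$contig
  res$target_start <- lo
  res$target_end <- hi
  if (g >= 0.8 * elem_len && g > 1.2 * ltr_len) {
    # the second condition keeps a solo-LTR-sized gap from qualifying when
    # the donor locus is itself a solo LTR (extent ~ one LTR)
    res$state <- "present_provirus"
  } else if (abs(g - ltr_len) <= 0.2 * ltr_len) {
    res$state <- "present_solo"
  } else if (abs(g) <= 25L) {
    res$state <- "absent_empty"
    if (g < 0 && -g >= 2L && -g <= 10L) {
      # junction overlap = the single target-site copy (forward strand)
      res$tsd_seq <- subseq0(target_genome[[pair$contig]], lo, hi)
    }
  }
  res
}

#' Call orthology states for all donor loci against a target genome
#'
#' Runs [make_probes()], [search_probe()], [pair_flank_hits()] and
#' [call_state()] for every locus. The search backend is the internal
#' seed-and-extend aligner; pre-computed hit tables can be substituted by
#' calling the stage functions directly.
#'
#' @param loci ERV locus data frame (donor genome annotation).
#' @param donor_genome,target_genome named character vectors of contig
#'   sequences.
#' @param ltr_len LTR length in bp.
#' @param target_species species label for the calls.
#' @param max_hits number of top-scoring hits kept per probe (default 10).
#' @param k seed length for the internal search (default 16).
#' @return a data frame of orthology calls, one row per locus.
#' @export
call_orthology <- function(loci, donor_genome, target_genome, ltr_len,
                           target_species = "target", max_hits = 10L,
                           k = 16L) {
  idx <- kmer_index(target_genome, k = k)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    pr <- make_probes(locus, donor_genome)
    if (!pr$p5$valid || !pr$p3$valid)
      return(call_state(NULL, locus, ltr_len, target_genome, target_species))
    h5 <- utils::head(search_probe(pr$p5$seq, idx, query_id = "5p"), max_hits)
    h3 <- utils::head(search_probe(pr$p3$seq, idx, query_id = "3p"), max_hits)
    pair <- pair_flank_hits(h5, h3, pr$p5$junction_offset,
                            pr$p3$junction_offset)
    call_state(pair, locus, ltr_len, target_genome, target_species)
  })
  do.call(rbind, rows)
}

#' Assign loci to species-tree branches by Dollo parsimony
#'
#' Each locus is placed on the branch above the most recent common ancestor
#' of the species in which it is present (a single gain; insertions do not
#' excise). A presence/absence pattern that would require a loss --
#' a species inside the clade called absent -- is flagged as a conflict
#' rather than silently assigned. Unresolved calls are ignored.
#'
#' @param calls orthology-call data frame covering every locus in every tip
#'   species of `tree` (states `present_provirus`, `present_solo`,
#'   `absent_empty`, `unresolved`).
#' @param tree a rooted `ape::phylo` whose tip labels match
#'   `calls$target_species`.
#' @return a list with `assignments` (data frame: `locus_id`, `branch` --
#'   "+"-joined tip labels of the clade -- and `conflict`) and `counts`
#'   (insertions per branch, conflicts excluded).
#' @export
orthology_matrix <- function(calls, tree) {
  stopifnot(inherits(tree, "phylo"))
  loci <- unique(calls$locus_id)
  rows <- lapply(loci, function(id) {
    sub <- calls[calls$locus_id == id, ]
    present <- sub$target_species[grepl("^present", sub$state)]
    absent <- sub$target_species[sub$state == "absent_empty"]
    if (length(present) == 0L)
      return(data.frame(locus_id = id, branch = NA_character_,
                        conflict = FALSE, stringsAsFactors = FALSE))
    if (length(present) == 1L) {
      clade_tips <- present
    } else {
      node <- ape::getMRCA(tree, present)
      clade_tips <- ape::extract.clade(tree, node)$tip.label
    }
    conflict <- any(absent %in% clade_tips)
    data.frame(locus_id = id,
               branch = paste(sort(clade_tips), collapse = "+"),
               conflict = conflict, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  ok <- assignments[!assignments$conflict & !is.na(assignments$branch), ]
  counts <- as.data.frame(table(branch = ok$branch),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n_insertions"
  list(assignments = assignments, counts = counts)
}
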