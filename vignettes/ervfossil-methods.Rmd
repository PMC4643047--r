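---
title: "ervfossil: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervfossil: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ervfossil` reconstructs the history of an endogenous retrovirus (ERV)
family from genome assemblies and repeat annotations. This vignette is the
package's own account of the science behind each stage: the models and
their assumptions, the tunable parameters with their defaults and units,
the numerical choices, and the places where the design was genuinely open.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Coordinate model and I/O

Internally every interval is 0-based, half-open, on the forward strand.
Conversions happen only at the format boundaries: RepeatMasker `.out` and
BLAST tabular are 1-based inclusive; BED is 0-based half-open. One internal
convention eliminates whole classes of off-by-one errors; the round-trip
tests (`.out` write/read, BED write/read) pin the boundary behaviour down.
For minus-strand RepeatMasker rows the consensus coordinates arrive as
`(left) end begin` and are normalised on read so `cons_start <= cons_end`
always holds. FASTA input is uppercased and IUPAC ambiguity codes collapse
to `N` (with a warning counting them) rather than erroring: WGS assemblies
contain them, and every downstream statistic already skips non-ACGT sites.

## Annotation

A *complete solo LTR* is a hit missing less than 150 bp at the consensus 5'
terminus and less than 10 bp at the 3' terminus — both rules strict, both
applied on consensus coordinates regardless of genomic strand (a hit with
internal deletions can still be terminally complete). A *putative
full-length provirus* is two same-strand, same-contig LTR hits separated by
3–10 kb of intervening sequence, measured exclusive of the LTRs, bounds
inclusive.

Two design points were open:

* **Fragment merging.** RepeatMasker splits single copies across rows.
  Before pairing, rows of one family/contig/strand are merged when they
  overlap by more than half the shorter row *or* when they look like
  fragments of one copy: genomic gap and consensus-coordinate step both
  within 50 bp (consensus runs against the genome on the minus strand).
* **Pairing in LTR chains.** When three or more LTR hits are mutually in
  range there is more than one way to pair them. `pair_ltrs` maximises the
  number of proviruses (exact search with memoisation per connected
  component of the eligibility graph; components above 15 hits fall back
  to a greedy scan), breaking ties by pairing the leftmost hit with its
  nearest eligible partner. A purely greedy leftmost-nearest scan looks
  natural but is not maximal — with window [3,10] kb and hits at 0, 3, 8
  and 10.9 kb it returns one pair where two exist — and on well-separated
  real or simulated elements the two agree anyway; the test suite checks
  maximality against an independent brute-force enumeration.

Unpaired hits that pass the completeness rule are reported as solo LTRs;
incomplete unpaired hits are dropped with a count. Family membership of a
candidate sequence uses best global-alignment identity to any current
member (matches over aligned columns, terminal gaps excluded so truncated
copies are not penalised), threshold 0.80 inclusive; candidates under 50 bp
are refused. Cross-species screening of search hits keeps those with at
least 80% identity over at least 80% of the query length.

## Orthology

Retroviral integration at the same host position twice is vanishingly
unlikely, and proviruses do not excise, so presence at an orthologous
position in two species means insertion before their divergence, and a
clean empty site means insertion after it. For each donor locus the package
extracts two probes — up to 200 bp of element terminus plus up to 200 bp of
host flank, in element orientation — records the element/host junction
offset, searches the target genome, pairs 5'/3' hits, and interprets the
signed junction gap `g`:

* `g >= 0.8 x` element length (and `> 1.2 x` LTR length): orthologous
  provirus;
* `|g - ltr_len| <= 0.2 x ltr_len`: orthologous solo LTR;
* `|g| <= 25` bp: pre-insertion empty site. At a true empty site the two
  junctions *overlap* by the target-site duplication, so `g` is about
  `-4`; an overlap of 2–10 bp is read out of the target as the TSD.
* anything else, or no pairable hits: unresolved.

These thresholds are package choices (the gap bands are disjoint by
construction and tolerant of small indels); the `1.2 x ltr_len` guard
exists because the provirus band is expressed relative to the donor extent,
which for a solo-LTR donor locus would otherwise swallow the solo band.
Hit pairing requires same contig and strand, junction separation of at
most 20 kb, and — because element termini are repetitive while flanks are
locus-specific — at least 20 bp of host-flank coverage per hit; candidate
pairs are ranked by flank-side coverage with total segment score as
tie-break. Ranking by raw score alone is fragile: a hit to an unrelated
element copy can extend a base or two past the junction by chance and
outscore the true site.

The default search backend is an exact 16-mer seed + ungapped
diagonal-extension aligner (maximum-scoring segment, match +1, mismatch
-2), adequate at desk scale for the no-indel regions the probes target; any
BLAST outfmt-6 table can be substituted, since downstream stages only
consume the hit-table contract. Minus-strand loci are handled by emitting
probes in element orientation and requiring strand *consistency* between
the paired hits, not absolute strand: orthology is strand-symmetric.

`orthology_matrix` places each locus on the species tree by Dollo parsimony
(single gain, no loss): the branch above the MRCA of the present species.
A pattern requiring a loss — absence inside the clade — is flagged as a
conflict rather than silently assigned; incomplete lineage sorting is not
modelled.

## Dating

A provirus integrates with two identical LTRs; each then accumulates
neutral substitutions independently, so with K2P distance `d` between them
and neutral rate `r` (substitutions/site/year), the insertion age is
`d / (2 r)`. The rate is a user-supplied constant (2.7e-9 for vesper bats,
1.8e-9 for felids, 2.2e-9 as a mammalian average); no rate estimation is
attempted. K2P uses transition proportion `P` and transversion proportion
`Q` over usable sites (gap and `N` columns skipped):
`d = -1/2 ln[(1-2P-Q) sqrt(1-2Q)]`, flagged saturated (d undefined) when a
log argument is non-positive and low-confidence below 50 usable sites.

**CpG masking.** Methylated CpG sites hypermutate and inflate apparent
divergence, so before the distance every alignment column that is part of a
CG dinucleotide in the ungapped sequence of *either* row is masked (the
ancestral state is unknown; the decayed TG/CA partner of a former CpG is
exactly the case the exclusion targets). A `mode = "first"` switch masks
relative to the first sequence only. One measured caveat guides how the
package validates the clock: on sequence with *no* CpG rate elevation the
either-row mask is not neutral — a mismatched column presents two chances
to sit in CpG context, so masking preferentially removes substituted
columns and deflates `d` by roughly a tenth at vespertilionid-like GC.
The parameter-recovery experiment therefore runs unmasked on its
CpG-neutral cohort, while the CpG-contrast experiment (multiplier 10)
checks the direction that motivates masking: masked estimates are closer
to truth than unmasked ones. On real, CpG-hypermutated data the masked
estimate is the defensible one; on CpG-quiet data it is conservative.

Alignment construction for an LTR pair is Needleman–Wunsch (match +1,
mismatch -1, gap open -5, extend -1) through Biostrings; the statistics are
defined on any supplied alignment, so the aligner is pluggable. Sliding
windows are 300 alignment columns advanced by 50 (the last partial window
dropped), reporting raw identity and K2P-corrected identity `1 - d` per
window.

## Gene conversion

For a provirus orthologous in species A and B, the four LTRs form a quartet
whose unrooted topology is diagnostic. Divergence accumulated between 5'
and 3' LTR before speciation makes the LTR-position grouping
{(5'A,5'B),(3'A,3'B)} the shorter tree; post-speciation conversion inside
each lineage erases that signal and makes the provirus grouping
{(5'A,3'A),(5'B,3'B)} shorter. The package resolves the quartet by the
four-point condition — smallest sum of CpG-masked K2P distances — instead
of maximum-likelihood trees with aLRT support: the discriminating signal is
purely topological and fully captured by the distance sums at this scale.
Support is the proportion of 1000 column-bootstrap replicates in which the
chosen pairing is strictly smallest; ties, saturated distances, or four
identical LTRs give a `star` verdict with support 0. Verdicts are
topology-only: no conversion-tract boundaries are estimated. An outgroup
LTR (explicitly supplied, as a non-orthologous family member) is carried
through the alignment for context but does not enter the four-point
statistic.

The detection-calibration experiment simulates the regime the test is
designed for: insertion 14 MY ago, speciation 10 MY ago (a
vespertilionid-like divergence), conversion in both lineages at a time
uniform in [1, 5] MY with tract fraction in [0.8, 1], 600 bp LTRs,
r = 2.7e-9. Conversions homogenising only a small tract, or occurring
immediately after speciation, leave progressively less signal and are not
the calibrated regime.

## Selection and integrity

dN/dS (ω) per coding domain uses Nei–Gojobori counting rather than codon
maximum likelihood — the package's largest method substitution, chosen
because the qualitative contrasts of interest (purifying vs relaxed;
envelope vs matrix) are reproducible with counting methods, and an adapter
can always ingest externally computed ML ω values for comparison.
Synonymous site counts per codon enumerate the nine single-base neighbours
with changes to stop codons excluded and per-position normalisation
(S + N = 3); observed differences average over the orderings of the
differing positions, paths through stop codons excluded. Proportions are
Jukes–Cantor corrected; dN and dS average over all sequence pairs;
analysis is restricted to codon columns where every sequence carries a
sense codon, refusing alignments with fewer than 30 such columns. The test
of ω = 1 resamples codon columns (1000 replicates, two-sided percentile
p-value, deterministic given a seed); per-domain p-values are reported raw
with no family-wise correction. `dS = 0` leaves ω undefined rather than
infinite.

The codon simulator used for calibration evolves a star tree of 10 taxa
over 300 codons at `kappa = 1` (no transition bias). That choice is
deliberate: NG86 site counting assumes unbiased substitution, and the
calibration experiments are meant to isolate ω recovery and test size, not
to re-measure the well-known NG86 bias under transition bias; the LTR
simulator keeps ti/tv = 2 where the K2P machinery corrects for it.
"Moderate divergence" is a 0.1 substitutions/site tip branch (about 0.2
pairwise).

ORF integrity counts, against the intact domain consensus that defines the
reading frame: frameshift events — contiguous indel runs whose length is
not a multiple of 3, one event regardless of length — and stop codons read
in the *locally restored* frame (cumulative indel offset divisible by 3),
so one frameshift is one event and does not cascade into spurious
downstream stops; a natural terminator in the final consensus codon is
excluded. The pooled event count over pooled codon exposure gets an exact
(Garwood) Poisson 95% interval: `qgamma(0.025, x)/n` to
`qgamma(0.975, x+1)/n`, zero-count upper bound `-ln(0.025)/n`. Exactness
makes the interval conservative (coverage at least the nominal level),
which the coverage experiment confirms empirically.

Shared deletion breakpoints — the signature of amplification from a
deletion-carrying progenitor — are found by collecting internal `-` runs of
at least 100 bp in sequences aligned to a common reference and clustering
them with 10 bp tolerance at each end; clusters of two or more are
reported. Terminal truncations are ignored.

## The simulator: what it emulates, and what it does not

`sim_erv_genomes` generates a shared ancestral host (i.i.d. bases at the
configured GC), plants insertions with 4 bp TSDs and two initially
identical LTRs, and evolves every LTR and internal region along its true
history: ancestral insertions evolve jointly until the 10 MY split and
independently afterwards, at the same host coordinate in both genomes;
solo LTRs replace a provirus with one LTR (the 5' lineage) plus TSD;
conversion events overwrite a tract of one LTR with the other at their
stated time. Substitution is per-site K2P (default r = 2.7e-9, ti/tv 2),
sampled exactly from the closed-form transition probabilities when the CpG
multiplier is 1 and otherwise discretised into 0.1 MY steps with CpG
context re-evaluated each step — the simplest process that produces the
inflation CpG masking corrects and lets it decay as CpG sites are lost.
Element geometry defaults to 600 bp LTRs and a 7 kb internal region,
inside the 3–10 kb pairing window. Insertion spacing exceeds the pairing
window (12 kb minimum) so planted elements cannot chain into spurious
proviruses, and insertions stay 500 bp from contig edges.

Deliberate non-realism, which bounds what passing tests show about real
data: no indel process outside explicit deletion/conversion events, so
aligner stress is minimal; the host background does not mutate, so flank
uniqueness is perfect and orthology search operates at its easiest; no
population genetics (every insertion fixes instantly); no assembly gaps;
emitted hit tables reflect true coordinates unless explicitly degraded
(`degrade_rm_out` adds fragmentation and terminal losses to exercise the
merge and completeness logic). Passing the orthology experiment, for
example, demonstrates the correctness of the junction logic, not
robustness to repeat-rich flanks or draft-assembly artefacts.

## Problem sizes and determinism

The validation experiments run at: 50 proviruses + 200 solo LTRs (plus
1000 random ≤8-hit pairing instances) for annotation; 500 LTR pairs per
age class {1, 5, 10, 20} MY and 500 CpG-contrast pairs for dating; 10,000
random alignments for the K2P oracle; a 10+10+10-insertion two-species
pair for orthology; 500 quartets for conversion; 30 replicates per ω plus
200 null simulations for selection; 10,000 Poisson draws for coverage; a
43-member family with 29 shared deletions. Every generator takes an
explicit seed and is byte-deterministic given its configuration; bootstrap
p-values and supports are deterministic given their seed arguments.

## Known limitations

* Solo-LTR recombinants are modelled as the surviving 5' LTR lineage, not
  as a true 5'/3' chimera; fine for copy-number and orthology truth,
  wrong for studying recombination breakpoints within solo LTRs.
* The orthology caller returns at most one site per locus per target
  genome; segmental duplications of an occupied locus would be missed.
* Nei–Gojobori ω is biased under transition bias and saturates at high
  divergence; the package reports the counting estimate and its bootstrap,
  nothing more.
* The quartet test assumes the four LTRs are alignable and unsaturated;
  it reports `star` rather than guessing when they are not.
* Dollo placement treats unresolved calls as missing data and flags, but
  does not resolve, patterns requiring loss (e.g. incomplete lineage
  sorting).
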