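---
title: "Models and methods behind releseq"
author: "releseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind releseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(releseq)
```

# The problem

RelE is a ribosome-dependent mRNA interferase: it binds the empty ribosomal
A site and cleaves the mRNA after the second nucleotide of the A-site
codon. This property has two consequences that this package quantifies.
First, in cells overexpressing RelE, repeated cycles of cleavage, rescue of
the stalled ribosome (tmRNA/ArfA) and reinitiation on intact messages
concentrate ribosome density toward the 5' end of genes and of
polycistronic operons. Second, because the cut position is pinned to the
A-site codon, footprints whose 3' ends are generated by RelE report the
ribosome's position — and its reading frame — at single-nucleotide
resolution, which conventional MNase digestion cannot do: MNase trims back
only to the ribosome boundary (about 12 nt beyond the A-site codon's first
nucleotide at the 3' side) and prefers to cut before A and T, blurring the
signal by several nucleotides.

`releseq` pairs a generative simulator of these processes with the analysis
stack used on real libraries: 3'-end density maps, equal-weighted metagene
profiles, operon position-ratio analysis, sub-codon frame quantification
with the NNC shift correction, a programmed-frameshift scan, and nuclease
sequence-specificity profiling. Every analysis can therefore be validated
against a known ground truth.

# The simulator

## Transcriptome

`generate_transcriptome()` builds a single contig carrying monocistronic
genes and polycistronic operons. Genes start with ATG, end with a stop
codon, are free of internal in-frame stops, and are drawn from a
configurable codon-usage table (uniform over the 61 sense codons by
default). Each transcription unit is transcribed with 50-nt 5' and 90-nt 3'
UTRs, placed on a random strand, and separated from its neighbours by
100-nt untranscribed spacers. All internal coordinates are 0-based,
half-open; GFF3 output is 1-based inclusive, SAM output follows its
standard.

One gene can be a prfB-like +1 frameshift construct: the annotated frame
stops at codon 28 (configurable) and the +1 frame, entered through prfB's
actual CTT-TGA-C shift window, continues for at least 50 sense codons. The
shift window is fixed rather than random for fidelity to prfB and because
it keeps the two reading frames locally distinguishable: flanking codons
ending in C would produce cuts that are frame-ambiguous under RelE's NNC
behaviour (below).

## Ribosome dynamics

`simulate_dynamics()` runs an exact event-driven stochastic simulation
(Gillespie) per mRNA copy, with exponential waiting times for: initiation
at an ORF whose start region is intact and whose first 10 codons are clear;
elongation by one codon under 10-codon steric exclusion (roughly one
footprint); termination when the stop codon occupies the A site; cleavage
of an unoccupied A site, which truncates the mRNA after the second
nucleotide of that codon, stalls the ribosome and removes the downstream
fragment from the initiable pool (it lacks a start-codon context for
reinitiation); and rescue, which removes stalled ribosomes. Ribosomes
downstream of a cut continue on their detached fragment until they
terminate or run into its end. A verbal kinetic scheme of this kind is most
faithfully rendered as a stochastic simulation: it needs no additional
closure assumptions and directly yields the read-level snapshots the
digestion model consumes.

Default rates are E. coli-like values chosen once: elongation 15 codons/s,
initiation 0.3/s per ORF, cleavage 0.1/s per exposed A site (so a ribosome
translates on the order of 100–150 codons before being hit, matching
enrichment within the first 100 codons), rescue 0.05/s, 30 mRNA copies per
unit, 150 s of simulated time. `IN_VITRO` mode freezes initiation and
elongation (chloramphenicol-arrested lysate): the snapshot is a static
occupancy — uniform over sense codons with 5% initiation complexes and 5%
termination complexes, matching the size of start/stop peaks in bacterial
profiling data — and is invariant under the simulated time.

## Digestion

`digest()` turns each ribosome into a footprint. The 5' end always follows
the MNase model (20 nt upstream of the A-site codon's first nucleotide).
The 3' end depends on the library:

* **RelE.** Non-NNC A-site codons are cut after their 2nd nucleotide
  (offset +1 from the codon's first nucleotide); codons ending in C ("NNC")
  are cut after their 3rd with probability `p_nnc` (default 1). The
  enzyme's context preference — C favoured at −1, G at +1 of the cut — is
  applied by acceptance–rejection *thinning*: a cleavage in a disfavoured
  context is less likely to be sampled into the library, but the position
  of a retained cut is never moved. This keeps A-site geometry exact (every
  retained non-NNC end is at +1, which downstream A-site inversion relies
  on) while reproducing the observed end-composition bias. The default
  weights (3 for each preference) are not quantified measurements; they are
  set so the bias matrices are visibly asymmetric, and are configurable. A
  `p_miscleave` floor (default 0) relocates that fraction of ends uniformly
  within the A-site codon, providing a controlled positional noise model.
  Ribosomes whose A site is stably occupied (bound tRNA or release factor,
  e.g. SecM- or TnaC-like complexes) block RelE with probability
  `p_block_occupied` and are digested back to the MNase boundary instead.
* **MNase.** Ends sit at the ribosome boundaries (+12 / −20 nt from the
  A-site codon's first nucleotide), with optional integer Gaussian jitter,
  and are repositioned within ±3 nt so that the realized cut sits
  immediately 5' of an A or T with probability `p_cut_before_AT` (0.8 by
  default; `NA` disables repositioning for pure geometry).

With the defaults this yields 22-nt RelE and 33-nt MNase footprints — an
11-nt difference set by the two 3' boundary offsets — inside the 20–40-nt
(in vivo) and 10–40-nt (in vitro) cloning windows applied by
`emit_reads()`. `simulate_rnaseq()` draws alkaline-hydrolysis-like
fragments: uniform starts, uniform lengths in 40–60 nt, no sequence bias at
either end.

# The analyses

**Density and metagenes.** Ribosome occupancy is assigned to the 3'-most
nucleotide of each read. Metagene profiles average density across genes
aligned at start or stop codons; each gene's window is mean-normalized
before averaging (so every gene carries equal weight regardless of
coverage) — raw-count averaging is available, since the equal-weighting
convention does not by itself dictate per-gene normalization. Genes under
1000 nt or with fewer than 0.1 reads per codon are excluded by default;
peak ties break toward 5' (they arise only in degenerate synthetic input).

**Polarity.** Per gene, the mean per-codon density over codons 1–100 is
compared with codons 151 to the end; 0.5 reads are added to the tail to
keep ratios finite. The median across genes is the recommended summary: the
mean of per-gene ratios is inflated by a few percent at realistic coverage
simply because a noisy denominator enters a ratio (Jensen's inequality),
which we verified by pushing coverage up until the median converged to 1
under a uniform model while the mean did not.

**Operons.** `define_single_TUs()` excludes monocistronic genes, operons
whose per-gene mean RNA-seq density varies more than 5-fold (strictly; such
operons likely contain internal promoters), and genes under 1 rpkm in any
supplied library. The mean per-nt density was chosen over the median for
the 5-fold filter (a flag provides the median). Position ratios are
treated/control mean densities, each normalized to its library total, and
the position-1 vs position-≥5 comparison uses the package's Mann–Whitney
test: midranks, tie-corrected variance, continuity correction, and exact
enumeration of all group assignments when the pooled sample size is at most
12. The exact branch uses the symmetric-distance convention for two-sided
p-values (the U null is symmetric, so this agrees with the
continuity-corrected normal branch to within 0.02 for continuous data at
the crossover size; with heavy ties the discrete null is lumpier and no
approximation does better than ~0.1 there).

**Reading frame.** Sub-codon positions are numbered 1/2/3 for the codon's
1st/2nd/3rd nucleotide. Frame fractions are computed over all CDSs without
a coverage floor, excluding 30 nt at each ORF end (start/stop peaks would
otherwise dominate); the 3'-UTR control keeps the frame of the preceding
ORF over 90 nt downstream of the stop, truncated at the next annotated
gene. The NNC shift moves density from the 3rd to the 2nd nucleotide of
every C-ending codon, exactly conserving totals; it is applied genome-wide
by default. A-site attribution inverts the digestion geometry and flags
position-3 ends on non-C-ending codons as ambiguous; the codon heatmap
drops ambiguous ends and reports their fraction rather than splitting them
fractionally.

**Frameshift scan.** The scan is a single-change-point binary segmentation
with a multinomial likelihood-ratio score, but the segment emission
probabilities are not the raw 3-category sub-codon composition: they are
the expected cut-position intensities implied by the nuclease model and the
gene sequence for "annotated frame up to codon m, then +1 (or −1) frame",
mixed with a small uniform mis-cleavage floor (2%). The sequence-aware
emissions matter because a cut after a C is consistent with a regular cut
in one frame *and* an NNC cut in another — composition alone cannot
distinguish them, and RelE's C preference enriches exactly those ends. With
plain composition categories the change point is localized to ±1 codon in
only ~76–86% of simulations at 200 reads; with model-based emissions the
same data yield ~98%. The reported codon is the last one decoded in the
annotated frame (codon 28 for the default construct). The call threshold of
10 on the likelihood-ratio score was frozen from no-shift calibration runs:
across hundreds of null simulations the maximum score stays at or below
zero (the alternative's extra parameters buy nothing under the null), while
genuine shifts score in the hundreds, so 10 sits far above the null's 99th
percentile with a wide margin and produced no false calls in 150 null
genes.

**Specificity.** `end_bias()` tabulates base frequencies at ±2 nt around
the cut in transcript orientation. The default background is the
coverage-weighted composition of the footprint bodies themselves, because
footprints sample expressed sequence, whose composition differs from the
whole genome by codon bias; a whole-genome background is available by
argument. Note that with `p_nnc = 1` the NNC rule alone — before any
context weights — produces C enrichment at −1 and G enrichment at +1,
because C-ending codons are diverted to the NNC cut and the +1 position of
a regular cut is then depleted of C; this is the mechanistic reading of the
observed bias, not an artifact.

# What the simulator does and does not establish

The generator reproduces the statistical structure the analyses rely on:
A-site-pinned 3' ends, boundary-pinned MNase ends with A/T preference,
5'-polarized in vivo occupancy from cleavage/rescue/reinitiation, uniform
RNA-seq fragments, and a prfB-like frameshift. It does not model rRNA/tRNA
contamination, sequencing errors, cloning/ligation bias, codon-specific
elongation pauses, or realistic E. coli sequence composition. Passing tests
therefore demonstrate that the analysis stack is correct and well
calibrated against the stated generative model — not that real libraries
are free of the artifacts the model omits (ligation bias in particular can
mimic nuclease preference and is deliberately out of scope).

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the targeted effects are unambiguous: 50 genes
with ~200 RelE footprints each for peak geometry (~10^4–10^5 reads);
100 seeds at ~200 observed footprints per gene for frameshift recovery and
for its matched no-shift control; 20 seeds of the dynamics for the polarity
contrasts; 10^5 fragments for the RNA-seq no-bias check; 2000 replicates
for the rank-sum type-I error. The same functions run unchanged at larger
sizes.

# A short session

```{r example, eval = FALSE}
tx <- generate_transcriptome(50, n_operons = 8, seed = 1)
snap <- simulate_dynamics(tx, ribosim_config("IN_VIVO", rng_seed = 2))
fp <- digest(snap, tx, "rele", seed = 3)
track <- assign_3prime_density(footprints_as_reads(fp), tx)
peak_offset(metagene(track, tx, "start"))          # 4 nt past the start
polarity_ratio(track, tx)$median                   # >> 1 under cleavage
shifted <- nnc_shift(track, tx, tx)
subcodon_fractions(shifted, tx)                    # f2 close to 1
```
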