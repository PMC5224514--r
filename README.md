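# releseq

Simulation and analysis of bacterial ribosome profiling libraries whose
footprint 3′ ends are generated by the mRNA interferase **RelE**.

RelE binds the empty ribosomal A site and cleaves the mRNA after the second
nucleotide of the A-site codon. Two things follow. In vivo, cycles of
cleavage, ribosome rescue and reinitiation pile ribosome density onto the
5′ ends of genes and operons. In profiling libraries, the cut position is
pinned to the A-site codon, so RelE-generated 3′ ends read out the
ribosome's position and reading frame at single-nucleotide resolution —
something MNase-only libraries cannot do, because MNase trims only to the
ribosome boundary (3′ end ≈ 12 nt past the first nucleotide of the A-site
codon) with a strong preference for cutting before A/T.

The geometry in brief, writing +k for "k nt downstream of the first
nucleotide of the anchor codon" (0-based): an initiation complex (start
codon in the P site, codon 2 in the A site) yields a RelE 3′ end at **+4**
and an MNase 3′ end at **+15** from the start codon; a termination complex
(stop codon in the A site) yields an MNase end at **+12** and a RelE end
at **+1** from the stop codon. Codons ending in C ("NNC" codons) are cut
by RelE after their **3rd** nucleotide instead; the *NNC shift* moves that
density back to the 2nd nucleotide and sharpens the frame signal, which is
what makes programmed frameshifts (such as the +1 shift at codon 28 of
*prfB*) directly visible in the data.

The package provides, as testable units behind one consistent interface:

* a synthetic transcriptome generator (FASTA/GFF3/operon TSV) with an
  optional prfB-like +1 frameshift construct;
* an exact stochastic simulator of translation with cleavage, rescue and
  reinitiation (Rcpp core), plus a frozen "in vitro" mode;
* nuclease digestion models (RelE and MNase) with configurable geometry,
  NNC behaviour and sequence preferences, SAM/FASTQ emission with
  per-read ground truth, and a uniform alkaline-hydrolysis RNA-seq model;
* 3′-end density tracks, equal-weighted metagene profiles with peak
  calling, per-gene expression filters (0.1 reads/codon, 1 rpkm), and
  5′/3′ polarity scores;
* operon analysis: single-transcription-unit filtering (5-fold RNA-seq
  rule), position-binned treated/control ratios, and a Mann–Whitney
  rank-sum test (exact below n = 12, tie-corrected normal otherwise);
* sub-codon frame tools: frame fractions with 30-nt ORF-end exclusion and
  a 3′-UTR control, A-site attribution, a 61-codon cleavage heatmap, the
  NNC shift, and a sequence-aware change-point scan for frameshifts;
* nuclease specificity profiling (end-bias matrices against a
  coverage-weighted background, ORF positional composition, length
  histograms, per-gene count robustness);
* `run_pipeline()`, a config-driven end-to-end run writing TSVs, BedGraph
  tracks and a machine-readable `summary.json`.

## Worked example

```r
library(releseq)

tx    <- generate_transcriptome(20, n_operons = 4,
                                gene_length_range = c(600, 900),
                                frameshift = frameshift_spec(), seed = 1)
snap  <- place_ribosomes(tx, 400, seed = 2)
fp    <- digest(snap, tx, "rele", seed = 3)
track <- assign_3prime_density(footprints_as_reads(fp), tx, label = "rele")

peak_offset(metagene(track, tx, "start", offsets = c(-20, 30),
                     min_gene_len = 450))
#> [1] 4

subcodon_fractions(track, tx)
#> <FrameSummary> cds_interior - 2239 reads; fractions 0.014/0.597/0.389

shifted <- nnc_shift(track, tx, tx)
subcodon_fractions(shifted, tx)
#> <FrameSummary> cds_interior - 2239 reads; fractions 0.014/0.979/0.007

frameshift_scan(track, "g0001", tx, genome = tx)
#>   gene_id codon frame_before frame_after direction    score
#> 1   g0001    29            2           3        +1 249.1011
```

Reading the output: the start-codon metagene peaks 4 nt past the first
nucleotide of the start codon — the RelE signature of initiation complexes
(codon 2 in the A site, cut after its 2nd nucleotide). Before correction,
60% of 3′ ends map to the 2nd sub-codon position and 39% to the 3rd (NNC
cuts); the NNC shift concentrates 98% of density on the 2nd position. The
change-point scan on the prfB-like gene calls a +1 frameshift with the
last annotated-frame codon at 29 (the construct's shift site is codon 28;
calls are accurate to about one codon at this coverage), with a
likelihood-ratio score of 249 against a no-shift model.

## Layout

```
R/              exported functions (one file per analysis stage)
src/            Rcpp Gillespie core for the translation dynamics
tests/testthat/ unit, property and end-to-end acceptance tests
scripts/        acceptance.R
vignettes/      releseq-methods.Rmd — models, assumptions, design choices
```
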