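# Shared fixtures, all built in code with fixed seeds.

# small multi-operon transcriptome used by several test files
tiny_tx <- function(seed = 101, n_genes = 12, n_operons = 2,
                    len = c(450, 900), ...) {
  generate_transcriptome(n_genes, n_operons = n_operons,
                         gene_length_range = len,
                         operon_size_range = c(2, 3), seed = seed, ...)
}

# single-gene transcriptome with the default prfB-like construct
fs_tx <- function(seed = 7) {
  generate_transcriptome(1, frameshift = frameshift_spec(), seed = seed)
}

# nuclease models with sequence effects disabled (exact geometry)
rele_plain <- function(...) nuclease_model("RELE", w_minus1_C = 1,
                                           w_plus1_G = 1, ...)
mnase_plain <- function(...) nuclease_model("MNASE", p_cut_before_AT = NA,
                                            boundary_jitter_sd = 0, ...)

# digest a uniform placement into a 3'-end density track
placement_track <- function(tx, n = 300, library_type = "rele",
                            seed = 11, digest_seed = 12, ...) {
  sn <- place_ribosomes(tx, n, seed = seed)
  fp <- digest(sn, tx, library_type = library_type, seed = digest_seed, ...)
  assign_3prime_density(footprints_as_reads(fp), tx)
}

# a DensityTrack with all-zero counts for a given genome
zero_track <- function(genome) {
  if (inherits(genome, "SyntheticTranscriptome")) genome <- genome$genome
  assign_3prime_density(
    data.frame(contig = character(), strand = character(),
               start = integer(), end = integer()), genome)
}

# put `count` 3' ends at a transcript-orientation CDS offset of a gene
add_ends <- function(track, g, off, count = 1) {
  pos <- if (g$strand == "+") g$start + off else g$end - 1 - off
  count <- as.integer(rep(count, length.out = length(pos)))
  track$counts[[g$contig]][[g$strand]][pos + 1] <-
    track$counts[[g$contig]][[g$strand]][pos + 1] + count
  track$total <- track$total + sum(count)
  track
}

# transcript-orientation 3'-end offset of footprints within their gene
fp_gene_offset <- function(fp, tx) {
  g <- tx$genes[match(fp$gene_id, tx$genes$gene_id), ]
  as.integer(ifelse(g$strand == "+", fp$three_pos - g$start,
                    g$end - 1 - fp$three_pos))
}

# two-gene operon with exact per-nt RNA densities set by hand
two_gene_operon_track <- function(dens, seed = 61) {
  tx <- generate_transcriptome(2, n_operons = 1,
                               operon_size_range = c(2, 2),
                               gene_length_range = c(300, 300),
                               seed = seed)
  tr <- zero_track(tx)
  for (i in 1:2) {
    g <- tx$genes[i, ]
    len <- g$end - g$start
    total <- round(dens[i] * len)
    counts <- rep(floor(total / len), len)
    extra <- total - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    tr <- add_ends(tr, g, 0:(len - 1), counts)
  }
  list(tx = tx, track = tr)
}

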