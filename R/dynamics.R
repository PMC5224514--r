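#' Place ribosomes on a transcriptome without dynamics
#'
#' Draws a static ribosome occupancy snapshot: a configurable fraction of
#' initiation complexes (start codon in P site, codon 2 in A site),
#' termination complexes (stop codon in the A site), and ribosomes uniform
#' over interior sense codons. For a frameshift gene the interior positions
#' follow the construct's ground truth: annotated-frame A sites up to the
#' internal stop, +1-frame A sites after it.
#'
#' @param tx A `SyntheticTranscriptome`.
#' @param reads_per_gene Ribosomes per gene.
#' @param frac_init,frac_term Fractions placed as initiation / termination
#'   complexes (termination is skipped for frameshift genes, whose annotated
#'   stop is not reached in the annotated frame).
#' @param p_occupied Probability a ribosome's A site is stably occupied.
#' @param genes Optional character vector restricting to some gene ids.
#' @param seed Optional integer seed.
#' @return A snapshot data frame with columns `tu_id`, `gene_id`, `a_off`
#'   (0-based nt offset of the A-site codon's first nucleotide from the CDS
#'   start, transcript orientation), `occupied`, `stalled`.
#' @export
place_ribosomes <- function(tx, reads_per_gene = 100L,
                            frac_init = 0.05, frac_term = 0.05,
                            p_occupied = 0, genes = NULL, seed = NULL) {
  stopifnot(inherits(tx, "SyntheticTranscriptome"))
  g <- tx$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  if (!nrow(g)) stop("no genes selected")
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      N <- g$n_codons[i]
      n <- reads_per_gene
      if (g$frameshift[i]) {
        fs <- g$fs_codon[i]
        interior <- c(3L * (1:(fs - 1L)),                    # A = codons 2..fs
                      3L * (fs - 1L) + 1L + 3L * (0:(g$fs_extend[i] - 1L)))
        n_term <- 0L
      } else {
        interior <- 3L * (1:(N - 2L))                        # A = codons 2..N-1
        n_term <- round(frac_term * n)
      }
      n_init <- round(frac_init * n)
      n_int <- n - n_init - n_term
      a <- c(rep(3L, n_init),
             if (n_term > 0) rep(3L * (N - 1L), n_term),
             interior[.sample_int(length(interior), n_int)])
      data.frame(tu_id = g$tu_id[i], gene_id = g$gene_id[i], a_off = a,
                 stringsAsFactors = FALSE)
    })
    snap <- do.call(rbind, rows)
    snap$occupied <- runif(nrow(snap)) < p_occupied
    snap$stalled <- FALSE
    snap
  })
}

#' Simulate ribosome dynamics under mRNA cleavage, rescue and reinitiation
#'
#' Runs an exact stochastic (event-driven) simulation of translation on every
#' transcription unit of a synthetic transcriptome. Ribosomes initiate at
#' each ORF when its start region is intact and clear, elongate codon by
#' codon with 10-codon steric exclusion, and terminate at stop codons.
#' Cleavage of an unoccupied A site truncates the mRNA after the second
#' nucleotide of the A-site codon, stalls the ribosome, and removes the
#' downstream fragment from the initiable pool; rescue removes stalled
#' ribosomes so their subunits can reinitiate elsewhere. These cycles of
#' cleavage, rescue and reinitiation concentrate ribosomes toward the 5' end
#' of genes and operons.
#'
#' In `IN_VITRO` mode (frozen positions; elongation/initiation arrested
#' before digestion) the returned snapshot is a static occupancy drawn by
#' [place_ribosomes()] and is invariant under `sim_time`.
#'
#' @param tx A `SyntheticTranscriptome`.
#' @param config A [ribosim_config()].
#' @return A snapshot data frame as in [place_ribosomes()] (one row per
#'   ribosome present at `sim_time`), with `stalled` marking ribosomes whose
#'   mRNA has been cleaved in their A site.
#' @export
simulate_dynamics <- function(tx, config = ribosim_config()) {
  stopifnot(inherits(tx, "SyntheticTranscriptome"),
            inherits(config, "RiboSimConfig"))
  if (config$mode == "IN_VITRO") {
    snap <- place_ribosomes(tx, config$in_vitro_ribosomes_per_gene,
                            frac_init = config$frac_init,
                            frac_term = config$frac_term,
                            p_occupied = config$p_occupied_Asite,
                            seed = config$rng_seed)
    attr(snap, "mode") <- "IN_VITRO"
    return(snap)
  }
  .with_seed(config$rng_seed, {
    out <- vector("list", nrow(tx$tus))
    for (k in seq_len(nrow(tx$tus))) {
      tu <- tx$tus$tu_id[k]
      members <- tx$genes[tx$genes$tu_id == tu, , drop = FALSE]
      members <- members[order(members$tx_offset), , drop = FALSE]
      res <- gillespie_tu_cpp(as.integer(members$tx_offset),
                              as.integer(members$n_codons),
                              as.integer(tx$tus$length[k]),
                              config$n_mrna_copies, config$sim_time,
                              config$k_init, config$k_elong,
                              config$k_cleave, config$k_rescue,
                              config$p_occupied_Asite, 30L)
      if (!nrow(res)) next
      out[[k]] <- data.frame(
        tu_id = tu,
        copy = res$copy,
        gene_id = members$gene_id[res$orf],
        a_off = 3L * res$codon,          # A site = P-site codon + 1
        occupied = res$occupied == 1L,
        stalled = res$state > 0L,
        stringsAsFactors = FALSE)
    }
    snap <- do.call(rbind, out)
    if (is.null(snap))
      snap <- data.frame(tu_id = character(), copy = integer(),
                         gene_id = character(),
                         a_off = integer(), occupied = logical(),
                         stalled = logical(), stringsAsFactors = FALSE)
    attr(snap, "mode") <- "IN_VIVO"
    snap
  })
}
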