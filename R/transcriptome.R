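#' Frameshift construct specification
#'
#' Describes a prfB-like programmed +1 frameshift gene: the annotated frame
#' carries an in-frame stop codon at `codon_index`, and a continuation open
#' reading frame in the +1 frame (starting at the second nucleotide of that
#' stop codon, as in prfB's CTT-TGA-C site) runs for `extend_codons` sense
#' codons.
#'
#' @param gene Index (into the generated gene list) of the gene carrying the
#'   frameshift. Default 1.
#' @param codon_index 1-based codon at which the annotated frame stops and
#'   the +1 frame takes over. Default 28, the prfB site.
#' @param extend_codons Number of sense codons in the +1-frame continuation
#'   (>= 50 for a realistic construct). Default 60.
#' @return A list of class `frameshift_spec`.
#' @export
frameshift_spec <- function(gene = 1L, codon_index = 28L, extend_codons = 60L) {
  if (codon_index < 3) stop("codon_index must be >= 3")
  if (extend_codons < 1) stop("extend_codons must be >= 1")
  structure(list(gene = as.integer(gene),
                 codon_index = as.integer(codon_index),
                 extend_codons = as.integer(extend_codons)),
            class = "frameshift_spec")
}

# one ordinary CDS: starts ATG, ends with a stop, no internal stops
.make_cds <- function(n_codons, usage) {
  sc <- names(usage)
  body <- sc[.sample_int(length(sc), n_codons - 2L, prob = usage)]
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

# prfB-like CDS: annotated-frame stop at codon fs, +1 ORF from nt 3*(fs-1)+1.
# The shift window reproduces prfB's CTT-TGA-C: Leu codon in the P site at
# the shift, TGA in frame 0, and the +1 frame resuming with GAC (Asp).
.make_fs_cds <- function(fs, extend, usage) {
  sc <- names(usage)
  pre <- sc[.sample_int(length(sc), fs - 2L, prob = usage)]
  pre[length(pre)] <- "CTT"
  shift1 <- "GAC"
  plus1 <- sc[.sample_int(length(sc), extend - 1L, prob = usage)]
  seq <- paste0("ATG", paste(pre, collapse = ""), "T", shift1,
                paste(plus1, collapse = ""), "TAA",  # +1-frame stop
                .random_nt(2L), "TAA")               # pad + annotated stop
  stopifnot(nchar(seq) %% 3 == 0)
  seq
}

#' Generate a synthetic transcriptome
#'
#' Builds a random bacterial-style transcriptome on a single contig: genes
#' grouped into operons (polycistronic transcription units) or monocistronic
#' units, each unit transcribed with fixed-length 5' and 3' UTRs, units
#' placed on alternating random strands and separated by untranscribed
#' spacers. Optionally one gene is a prfB-like +1 frameshift construct (see
#' [frameshift_spec()]). Serves as ground truth for footprint simulation and
#' for all downstream analyses.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_operons Number of polycistronic operons; genes not assigned to an
#'   operon are monocistronic.
#' @param gene_length_range Range (nt) of CDS lengths; realized lengths are
#'   multiples of 3.
#' @param codon_usage Named probability vector over the 61 sense codons
#'   (default uniform).
#' @param frameshift A [frameshift_spec()] or NULL.
#' @param utr5_len,utr3_len UTR lengths (nt) per transcription unit.
#' @param operon_size_range Range of genes per operon.
#' @param intergenic_len Untranslated nt between CDSs within an operon.
#' @param spacer_len Untranscribed nt between transcription units.
#' @param contig_name Name of the single contig.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An object of class `SyntheticTranscriptome`: a list with
#'   `genome` (a [Biostrings::DNAStringSet]), `genes` (data frame, 0-based
#'   half-open genomic CDS coordinates), `tus` (transcription units),
#'   `operons` (long-format operon table), `tx_seq` (per-unit transcript
#'   sequences) and the UTR lengths.
#' @examples
#' tx <- generate_transcriptome(4, n_operons = 1, seed = 1)
#' tx$genes[, c("gene_id", "strand", "start", "end", "operon_id")]
#' @export
generate_transcriptome <- function(n_genes, n_operons = 0L,
                                   gene_length_range = c(300L, 1200L),
                                   codon_usage = NULL,
                                   frameshift = NULL,
                                   utr5_len = 50L, utr3_len = 90L,
                                   operon_size_range = c(2L, 5L),
                                   intergenic_len = 20L, spacer_len = 100L,
                                   contig_name = "chrSim",
                                   seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  usage <- .check_codon_usage(codon_usage)
  if (!is.null(frameshift) && !inherits(frameshift, "frameshift_spec"))
    frameshift <- do.call(frameshift_spec, as.list(frameshift))
  .with_seed(seed, {
    cod_rng <- pmax(2L, round(gene_length_range / 3))
    # operon membership: operons take consecutive gene indices
    sizes <- integer(0)
    if (n_operons > 0) {
      sizes <- .sample_int(operon_size_range[2] - operon_size_range[1] + 1L,
                           n_operons) + operon_size_range[1] - 1L
      if (sum(sizes) > n_genes)
        stop("impossible constraints: operons require ", sum(sizes),
             " genes but n_genes = ", n_genes)
    }
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    op_of <- rep(NA_character_, n_genes)
    pos_of <- rep(NA_integer_, n_genes)
    idx <- 1L
    for (k in seq_along(sizes)) {
      members <- idx:(idx + sizes[k] - 1L)
      op_of[members] <- sprintf("op%03d", k)
      pos_of[members] <- seq_along(members)
      idx <- idx + sizes[k]
    }
    # per-gene CDS sequences
    n_cod <- .sample_int(cod_rng[2] - cod_rng[1] + 1L, n_genes) +
      cod_rng[1] - 1L
    cds <- character(n_genes)
    is_fs <- rep(FALSE, n_genes)
    fs_codon <- rep(NA_integer_, n_genes)
    fs_extend <- rep(NA_integer_, n_genes)
    for (i in seq_len(n_genes)) {
      if (!is.null(frameshift) && i == frameshift$gene) {
        cds[i] <- .make_fs_cds(frameshift$codon_index,
                               frameshift$extend_codons, usage)
        is_fs[i] <- TRUE
        fs_codon[i] <- frameshift$codon_index
        fs_extend[i] <- frameshift$extend_codons
        n_cod[i] <- nchar(cds[i]) %/% 3L
      } else {
        cds[i] <- .make_cds(n_cod[i], usage)
      }
    }
    # assemble transcription units (one per monocistronic gene / operon)
    tu_members <- split(seq_len(n_genes),
                        ifelse(is.na(op_of), gene_ids, op_of))
    tu_members <- tu_members[order(vapply(tu_members, min, 1L))]
    tu_ids <- sprintf("tu%03d", seq_along(tu_members))
    tx_seq <- character(length(tu_members))
    tx_off <- integer(n_genes)
    tu_of_gene <- character(n_genes)
    for (k in seq_along(tu_members)) {
      members <- tu_members[[k]]
      parts <- character(0)
      off <- utr5_len
      for (j in seq_along(members)) {
        i <- members[j]
        tx_off[i] <- off
        tu_of_gene[i] <- tu_ids[k]
        parts <- c(parts, cds[i])
        off <- off + nchar(cds[i])
        if (j < length(members)) {
          parts <- c(parts, .random_nt(intergenic_len))
          off <- off + intergenic_len
        }
      }
      tx_seq[k] <- paste0(.random_nt(utr5_len), paste(parts, collapse = ""),
                          .random_nt(utr3_len))
    }
    names(tx_seq) <- tu_ids
    # place units on the contig
    tu_strand <- sample(c("+", "-"), length(tu_ids), replace = TRUE)
    tu_start <- integer(length(tu_ids))
    cur <- spacer_len
    genome_parts <- .random_nt(spacer_len)
    for (k in seq_along(tu_ids)) {
      tu_start[k] <- cur
      gseq <- if (tu_strand[k] == "+") tx_seq[k] else .revcomp(tx_seq[k])
      genome_parts <- c(genome_parts, gseq, .random_nt(spacer_len))
      cur <- cur + nchar(tx_seq[k]) + spacer_len
    }
    tu_len <- nchar(tx_seq)
    tus <- data.frame(tu_id = tu_ids, contig = contig_name,
                      strand = tu_strand, start = tu_start,
                      end = tu_start + tu_len, length = unname(tu_len),
                      stringsAsFactors = FALSE)
    # genomic CDS coordinates from transcript offsets
    gstart <- gend <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      k <- match(tu_of_gene[i], tu_ids)
      L <- nchar(cds[i])
      if (tu_strand[k] == "+") {
        gstart[i] <- tu_start[k] + tx_off[i]
        gend[i] <- gstart[i] + L
      } else {
        gend[i] <- tu_start[k] + tu_len[k] - tx_off[i]
        gstart[i] <- gend[i] - L
      }
    }
    genes <- data.frame(gene_id = gene_ids, contig = contig_name,
                        strand = tu_strand[match(tu_of_gene, tu_ids)],
                        start = gstart, end = gend,
                        tu_id = tu_of_gene, operon_id = op_of,
                        operon_position = pos_of,
                        tx_offset = tx_off, n_codons = as.integer(n_cod),
                        frameshift = is_fs, fs_codon = fs_codon,
                        fs_extend = fs_extend, cds_seq = cds,
                        stringsAsFactors = FALSE)
    operons <- genes[!is.na(genes$operon_id),
                     c("operon_id", "gene_id", "operon_position")]
    names(operons)[3] <- "position"
    rownames(operons) <- NULL
    genome <- Biostrings::DNAStringSet(
      setNames(paste(genome_parts, collapse = ""), contig_name))
    structure(list(genome = genome, genes = genes, tus = tus,
                   operons = operons, tx_seq = tx_seq,
                   utr5_len = as.integer(utr5_len),
                   utr3_len = as.integer(utr3_len)),
              class = "SyntheticTranscriptome")
  })
}

#' @export
print.SyntheticTranscriptome <- function(x, ...) {
  cat("<SyntheticTranscriptome>", length(x$genes$gene_id), "genes in",
      nrow(x$tus), "transcription units;",
      sum(!is.na(x$genes$operon_id)), "genes in",
      length(unique(stats::na.omit(x$genes$operon_id))), "operons;",
      "contig of", sum(Biostrings::width(x$genome)), "nt\n")
  if (any(x$genes$frameshift))
    cat("  frameshift gene:",
        x$genes$gene_id[x$genes$frameshift], "(+1 at codon",
        x$genes$fs_codon[x$genes$frameshift], ")\n")
  invisible(x)
}

# GRanges of CDS features with operon attributes
.genes_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$operon_id <- genes$operon_id
  S4Vectors::mcols(gr)$operon_position <- as.character(genes$operon_position)
  gr
}

#' Write a synthetic transcriptome to standard files
#'
#' Emits the genome as FASTA, the CDS annotation as GFF3 (1-based inclusive
#' coordinates, `gene_id` / `operon_id` / `operon_position` attributes) and
#' the operon table as TSV (`operon_id`, `gene_id`, `position`).
#'
#' @param tx A `SyntheticTranscriptome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_transcriptome <- function(tx, dir, prefix = "sim") {
  stopifnot(inherits(tx, "SyntheticTranscriptome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, "_genome.fa"))
  gff <- file.path(dir, paste0(prefix, "_annotation.gff3"))
  tsv <- file.path(dir, paste0(prefix, "_operons.tsv"))
  Biostrings::writeXStringSet(tx$genome, fasta)
  rtracklayer::export(.genes_granges(tx$genes), gff, format = "gff3")
  write.table(tx$operons, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, gff = gff, operons = tsv))
}

# transcript-orientation CDS sequence of one gene
.gene_cds_seq <- function(tx, gene_id) {
  g <- tx$genes[match(gene_id, tx$genes$gene_id), ]
  substr(tx$tx_seq[[g$tu_id]], g$tx_offset + 1L, g$tx_offset + (g$end - g$start))
}
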