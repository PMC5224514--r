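# Standard-format ingestion: FASTA genomes, GFF3 + operon annotation, SAM
# alignments. Internal convention everywhere: 0-based half-open coordinates.

#' Load a genome FASTA
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], uppercase, indexed by contig name
#'   (first word of each header).
#' @export
load_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(genome)) stop("no sequences in ", fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names in ", fasta_path)
  Biostrings::DNAStringSet(toupper(genome))
}

#' Load gene annotation (GFF3) and an operon table
#'
#' Reads CDS features from a GFF3 file (1-based inclusive coordinates,
#' converted to the package's 0-based half-open convention) and optionally a
#' RegulonDB-style operon TSV (`operon_id`, `gene_id`, `position`). CDS
#' records whose length is not a multiple of 3 are excluded with a warning;
#' operon rows naming unknown genes are skipped with a warning. Operon
#' membership in the TSV takes precedence over `operon_id` attributes in the
#' GFF.
#'
#' @param gff_path Path to a GFF3 file with CDS features carrying a
#'   `gene_id` (or `ID`) attribute.
#' @param operon_tsv Optional path to the operon table.
#' @return An object of class `AnnotationSet`: list with `genes` (data frame
#'   with 0-based half-open `start`/`end`, `n_codons`, operon columns) and
#'   `operons`.
#' @export
load_annotation <- function(gff_path, operon_tsv = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (!length(gr)) stop("no CDS features in ", gff_path)
  ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
  if (is.null(ids) || anyNA(ids)) stop("CDS features lack gene_id/ID")
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", gff_path)
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,      # GFF is 1-based inclusive
    end = GenomicRanges::end(gr),
    operon_id = if (!is.null(gr$operon_id)) as.character(gr$operon_id)
                else NA_character_,
    operon_position = if (!is.null(gr$operon_position))
      suppressWarnings(as.integer(gr$operon_position)) else NA_integer_,
    stringsAsFactors = FALSE)
  bad <- (genes$end - genes$start) %% 3L != 0L
  if (any(bad)) {
    warning("excluding ", sum(bad), " CDS with length not divisible by 3: ",
            paste(head(genes$gene_id[bad], 5), collapse = ", "))
    genes <- genes[!bad, , drop = FALSE]
  }
  genes$n_codons <- (genes$end - genes$start) %/% 3L
  operons <- NULL
  if (!is.null(operon_tsv)) {
    operons <- read.delim(operon_tsv, stringsAsFactors = FALSE)
    .stopifnot_cols(operons, c("operon_id", "gene_id", "position"),
                    "operon table")
    unknown <- !operons$gene_id %in% genes$gene_id
    if (any(unknown)) {
      warning("operon table names ", sum(unknown),
              " unknown gene(s), skipped: ",
              paste(head(operons$gene_id[unknown], 5), collapse = ", "))
      operons <- operons[!unknown, , drop = FALSE]
    }
    genes$operon_id <- operons$operon_id[match(genes$gene_id, operons$gene_id)]
    genes$operon_position <-
      operons$position[match(genes$gene_id, operons$gene_id)]
  } else if (any(!is.na(genes$operon_id))) {
    operons <- genes[!is.na(genes$operon_id),
                     c("operon_id", "gene_id", "operon_position")]
    names(operons)[3] <- "position"
    rownames(operons) <- NULL
  }
  structure(list(genes = genes, operons = operons), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("<AnnotationSet>", nrow(x$genes), "genes;",
      if (is.null(x$operons)) 0L else length(unique(x$operons$operon_id)),
      "operons\n")
  invisible(x)
}

# accept either an AnnotationSet or a SyntheticTranscriptome
.ann_genes <- function(annotation) {
  if (inherits(annotation, "SyntheticTranscriptome") ||
      inherits(annotation, "AnnotationSet")) return(annotation$genes)
  if (is.data.frame(annotation)) return(annotation)
  stop("annotation must be an AnnotationSet, SyntheticTranscriptome, ",
       "or gene data frame")
}

# reference-space width of simple CIGAR strings (M/D/N/=/X consume reference)
.cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Load aligned reads from SAM
#'
#' Converts the SAM to BAM internally (the file on disk is untouched) and
#' iterates mapped records. With `unique_only`, secondary and supplementary
#' alignments and records below `min_mapq` are dropped; counts of dropped
#' records are reported as messages.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param unique_only Keep only primary, uniquely-mapping records.
#' @param min_mapq Mapping-quality floor applied when `unique_only`.
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when given,
#'   alignment contigs must all be present in it.
#' @return A data frame of reads: `contig`, `strand`, `start` (0-based),
#'   `end` (exclusive), `mapq`, `flag`.
#' @export
load_alignments <- function(sam_path, unique_only = TRUE, min_mapq = 0L,
                            genome = NULL) {
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("flag", "mapq")))
  flag <- S4Vectors::mcols(ga)$flag
  mapq <- S4Vectors::mcols(ga)$mapq
  n0 <- length(ga)
  keep <- rep(TRUE, n0)
  if (unique_only) {
    keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L &
      (is.na(mapq) | mapq >= min_mapq)
    if (any(!keep))
      message("load_alignments: dropped ", sum(!keep),
              " non-primary/low-MAPQ record(s)")
  }
  ga <- ga[keep]
  reads <- data.frame(
    contig = as.character(GenomicRanges::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    start = GenomicRanges::start(ga) - 1L,
    end = GenomicRanges::end(ga),
    mapq = mapq[keep], flag = flag[keep],
    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    bad <- setdiff(unique(reads$contig), names(genome))
    if (length(bad))
      stop("alignment contig(s) absent from genome: ",
           paste(bad, collapse = ", "))
  }
  message("load_alignments: ", nrow(reads), " of ", n0, " records retained")
  reads
}

#' Convert footprints to a read data frame
#'
#' @param footprints Footprint data frame from [digest()] or
#'   [simulate_rnaseq()].
#' @return Data frame with `contig`, `strand`, `start` (0-based), `end`
#'   (exclusive) as consumed by [assign_3prime_density()].
#' @export
footprints_as_reads <- function(footprints) {
  footprints[, c("contig", "strand", "start", "end")]
}
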