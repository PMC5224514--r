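# Nuclease sequence-specificity profiling: nucleotide bias around footprint
# 3' ends, ORF positional base composition, length histograms, and per-gene
# count robustness between libraries.

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Nucleotide bias around footprint 3' ends
#'
#' Tabulates base frequencies at positions -`flank`..+`flank` around the
#' cleavage site (the cut lies between the footprint's last nucleotide,
#' position -1, and the next nucleotide, position +1), in transcript
#' orientation, and compares them to a background composition. The default
#' background is the coverage-weighted composition of the footprint bodies
#' themselves (footprints sample expressed sequence); `"genome"` uses the
#' strand-symmetric whole-genome composition.
#'
#' @param footprints Footprint data frame (needs `contig`, `strand`,
#'   `three_pos`, `start`, `end`).
#' @param genome Genome ([Biostrings::DNAStringSet] or
#'   `SyntheticTranscriptome`).
#' @param flank Positions examined each side of the cut (default 2).
#' @param background `"coverage"` or `"genome"`.
#' @return Object of class `EndBiasMatrix`: `freq` (positions x ACGT, rows
#'   sum to 1), `background`, `enrichment` (= freq / background; `NA` and
#'   flagged where the background frequency is 0), `n_used`, `n_skipped`.
#' @export
end_bias <- function(footprints, genome, flank = 2L,
                     background = c("coverage", "genome")) {
  if (inherits(genome, "SyntheticTranscriptome")) genome <- genome$genome
  background <- match.arg(background)
  .stopifnot_cols(footprints, c("contig", "strand", "three_pos"),
                  "footprints")
  fp <- footprints
  lens <- setNames(Biostrings::width(genome), names(genome))
  # skip ends too close to a contig edge to resolve the full flank
  ok <- fp$three_pos - flank >= 0L &
    fp$three_pos + flank < lens[fp$contig]
  n_skipped <- sum(!ok)
  fp <- fp[ok, , drop = FALSE]
  if (!nrow(fp)) stop("no usable 3' ends")
  positions <- setdiff(seq.int(-flank, flank), 0L)
  freq <- matrix(0, length(positions), 4,
                 dimnames = list(positions, c("A", "C", "G", "T")))
  gstr <- setNames(as.character(genome), names(genome))
  for (j in seq_along(positions)) {
    p <- positions[j]
    d <- if (p < 0) p + 1L else p
    pos <- ifelse(fp$strand == "+", fp$three_pos + d, fp$three_pos - d)
    nt <- substr(gstr[fp$contig], pos + 1L, pos + 1L)
    minus <- fp$strand == "-"
    nt[minus] <- .COMP[nt[minus]]
    tab <- table(factor(nt, levels = c("A", "C", "G", "T")))
    freq[j, ] <- as.numeric(tab) / sum(tab)
  }
  if (background == "coverage") {
    body <- Biostrings::subseq(genome[fp$contig], start = fp$start + 1L,
                               end = fp$end)
    minus <- fp$strand == "-"
    if (any(minus))
      body[minus] <- Biostrings::reverseComplement(body[minus])
    bg <- colSums(Biostrings::letterFrequency(body, c("A", "C", "G", "T")))
  } else {
    fwd <- colSums(Biostrings::letterFrequency(genome,
                                               c("A", "C", "G", "T")))
    bg <- fwd + fwd[c("T", "G", "C", "A")]   # strand-symmetric
    names(bg) <- c("A", "C", "G", "T")
  }
  bg <- bg / sum(bg)
  enr <- sweep(freq, 2, bg, "/")
  flagged <- names(bg)[bg == 0]
  enr[, bg == 0] <- NA_real_
  structure(list(freq = freq, background = bg, enrichment = enr,
                 n_used = nrow(fp), n_skipped = n_skipped,
                 flagged = flagged),
            class = "EndBiasMatrix")
}

#' @export
print.EndBiasMatrix <- function(x, ...) {
  cat("<EndBiasMatrix>", x$n_used, "ends (", x$n_skipped, "skipped )\n")
  print(round(x$enrichment, 3))
  invisible(x)
}

#' Nucleotide composition by sub-codon position over all ORFs
#'
#' @param genome Genome.
#' @param annotation Annotation.
#' @return 3 x 4 matrix of frequencies (rows = codon positions 1..3,
#'   columns = A/C/G/T; rows sum to 1).
#' @export
orf_position_bias <- function(genome, annotation) {
  genes <- .ann_genes(annotation)
  counts <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3),
                                            c("A", "C", "G", "T")))
  for (i in seq_len(nrow(genes))) {
    chars <- strsplit(.cds_seq_genome(genome, genes[i, ]), "")[[1]]
    pos <- (seq_along(chars) - 1L) %% 3L + 1L
    for (p in 1:3) {
      tab <- table(factor(chars[pos == p], levels = c("A", "C", "G", "T")))
      counts[p, ] <- counts[p, ] + as.numeric(tab)
    }
  }
  counts / rowSums(counts)
}

#' Footprint length histogram
#'
#' @param footprints Footprint data frame with `length` (and optionally a
#'   `nuclease` label column).
#' @return List with `histogram` (data frame `library`, `length`, `count`)
#'   and `median` (named per library).
#' @export
length_histogram <- function(footprints) {
  if (!nrow(footprints))
    return(list(histogram = data.frame(library = character(),
                                       length = integer(),
                                       count = integer()),
                median = numeric(0)))
  lib <- if (!is.null(footprints$nuclease)) footprints$nuclease
         else rep("all", nrow(footprints))
  tab <- as.data.frame(table(library = lib, length = footprints$length),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  hist <- data.frame(library = tab$library,
                     length = as.integer(tab$length),
                     count = tab$Freq, stringsAsFactors = FALSE)
  med <- vapply(split(footprints$length, lib), median, 0)
  list(histogram = hist[order(hist$library, hist$length), ], median = med)
}

#' Correlation of per-gene counts between two libraries
#'
#' @param track_a,track_b `DensityTrack`s.
#' @param annotation Annotation.
#' @param min_reads Genes must have at least this many 3' ends in both
#'   tracks (default 10).
#' @return List with `n_genes`, `pearson_log` (Pearson correlation of log
#'   counts) and `spearman`.
#' @export
per_gene_correlation <- function(track_a, track_b, annotation,
                                 min_reads = 10L) {
  genes <- .ann_genes(annotation)
  ta <- gene_stats(track_a, genes, min_reads_per_codon = NULL)$stats$total
  tb <- gene_stats(track_b, genes, min_reads_per_codon = NULL)$stats$total
  keep <- ta >= min_reads & tb >= min_reads
  if (sum(keep) < 3L)
    stop("fewer than 3 genes pass min_reads in both tracks")
  list(n_genes = sum(keep),
       pearson_log = cor(log(ta[keep]), log(tb[keep])),
       spearman = cor(ta[keep], tb[keep], method = "spearman"))
}
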