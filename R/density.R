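# 3'-end density tracks, gene-level statistics and filters, equal-weighted
# metagene profiles, peak calling, and gene polarity scores.

#' Build a 3'-end density track
#'
#' Assigns ribosome occupancy to the 3' end of every read: a forward-strand
#' read covering `[start, end)` increments position `end - 1` on the "+"
#' track, a reverse-strand read increments `start` on the "-" track.
#'
#' @param reads Data frame with `contig`, `strand`, `start`, `end` (0-based
#'   half-open), e.g. from [load_alignments()] or [footprints_as_reads()].
#' @param genome [Biostrings::DNAStringSet] (or `SyntheticTranscriptome`)
#'   providing contig lengths.
#' @param label Library label stored on the track.
#' @return An object of class `DensityTrack`: per contig and strand, integer
#'   counts at each nucleotide; `total` equals the number of reads.
#' @export
assign_3prime_density <- function(reads, genome, label = "") {
  if (inherits(genome, "SyntheticTranscriptome")) genome <- genome$genome
  .stopifnot_cols(reads, c("contig", "strand", "start", "end"), "reads")
  lens <- setNames(Biostrings::width(genome), names(genome))
  counts <- lapply(lens, function(L)
    list("+" = integer(L), "-" = integer(L)))
  pos <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  for (ctg in unique(reads$contig)) {
    for (st in c("+", "-")) {
      sel <- reads$contig == ctg & reads$strand == st
      if (!any(sel)) next
      tab <- tabulate(pos[sel] + 1L, nbins = lens[[ctg]])
      counts[[ctg]][[st]] <- counts[[ctg]][[st]] + tab
    }
  }
  structure(list(counts = counts, lengths = lens,
                 total = nrow(reads), label = label),
            class = "DensityTrack")
}

#' @export
print.DensityTrack <- function(x, ...) {
  cat("<DensityTrack>", if (nzchar(x$label)) paste0("'", x$label, "' "),
      sum(vapply(x$counts, function(ct) sum(ct[["+"]]) + sum(ct[["-"]]), 0)),
      "3' ends on", length(x$counts), "contig(s)\n")
  invisible(x)
}

# counts over one gene in transcript orientation (position 1 = first CDS nt)
.gene_vec <- function(track, g) {
  v <- track$counts[[g$contig]][[g$strand]][(g$start + 1L):g$end]
  if (g$strand == "-") rev(v) else v
}

# replace the counts over one gene (transcript orientation in, genomic out)
.set_gene_vec <- function(track, g, v) {
  if (g$strand == "-") v <- rev(v)
  track$counts[[g$contig]][[g$strand]][(g$start + 1L):g$end] <- v
  track
}

# genomic position of a transcript-orientation offset from an anchor
.anchor_pos <- function(g, anchor) {
  if (anchor == "start") {
    if (g$strand == "+") g$start else g$end - 1L
  } else {                       # first nt of the stop codon
    if (g$strand == "+") g$end - 3L else g$start + 2L
  }
}

#' Per-gene density statistics and expression filters
#'
#' Computes, per gene, the total 3'-end count within the CDS, reads per
#' codon, and rpkm (reads per kb of CDS per million reads in the track), and
#' applies the profiling expression filters: genes with fewer than
#' `min_reads_per_codon` reads per codon (default 0.1, strict inequality)
#' are excluded, as are genes below `min_rpkm` when given.
#'
#' @param track A `DensityTrack`.
#' @param annotation `AnnotationSet`, `SyntheticTranscriptome` or gene data
#'   frame.
#' @param min_reads_per_codon Exclusion threshold (genes with strictly fewer
#'   reads per codon are dropped); `NULL` disables.
#' @param min_rpkm Optional rpkm floor (strictly-below excluded).
#' @return List with `stats` (per-gene data frame with `pass` and `reason`),
#'   and `retained` (character vector of passing gene ids).
#' @export
gene_stats <- function(track, annotation, min_reads_per_codon = 0.1,
                       min_rpkm = NULL) {
  genes <- .ann_genes(annotation)
  total <- vapply(seq_len(nrow(genes)), function(i)
    sum(.gene_vec(track, genes[i, ])), 0)
  n_cod <- (genes$end - genes$start) %/% 3L
  rpc <- total / n_cod
  rpkm <- total / ((genes$end - genes$start) / 1000) /
    (max(track$total, 1L) / 1e6)
  pass <- rep(TRUE, nrow(genes))
  reason <- rep(NA_character_, nrow(genes))
  if (!is.null(min_reads_per_codon)) {
    low <- rpc < min_reads_per_codon
    reason[low & pass] <- sprintf("reads_per_codon < %g", min_reads_per_codon)
    pass <- pass & !low
  }
  if (!is.null(min_rpkm)) {
    low <- rpkm < min_rpkm
    reason[low & pass] <- sprintf("rpkm < %g", min_rpkm)
    pass <- pass & !low
  }
  stats <- data.frame(gene_id = genes$gene_id, total = total,
                      n_codons = n_cod, reads_per_codon = rpc, rpkm = rpkm,
                      pass = pass, reason = reason, stringsAsFactors = FALSE)
  list(stats = stats, retained = genes$gene_id[pass])
}

#' Equal-weighted metagene profile
#'
#' Averages 3'-end density across genes aligned at their start or stop
#' codons (anchor = first nucleotide of the codon, offset 0), in transcript
#' orientation. Genes shorter than `min_gene_len` or failing the
#' reads-per-codon filter are excluded. With `normalization = "mean"`
#' (default) each gene's window is divided by its mean before averaging so
#' every gene contributes equal weight regardless of coverage; `"raw"`
#' averages raw counts.
#'
#' @param track A `DensityTrack`.
#' @param annotation Annotation (see [gene_stats()]).
#' @param anchor `"start"` or `"stop"`.
#' @param offsets `c(left, right)` window of offsets relative to the anchor
#'   (negative = upstream in transcript orientation).
#' @param min_gene_len Minimum CDS length (nt), default 1000.
#' @param normalization `"mean"` or `"raw"`.
#' @param min_reads_per_codon Expression filter (see [gene_stats()]).
#' @return Object of class `MetageneProfile`: list with `offset`, `mean`
#'   (average density per offset), `n_genes`, `anchor`, `normalization`.
#' @export
metagene <- function(track, annotation, anchor = c("start", "stop"),
                     offsets = c(-50L, 100L), min_gene_len = 1000L,
                     normalization = c("mean", "raw"),
                     min_reads_per_codon = 0.1) {
  anchor <- match.arg(anchor)
  normalization <- match.arg(normalization)
  genes <- .ann_genes(annotation)
  off <- seq.int(offsets[1], offsets[2])
  keep <- (genes$end - genes$start) >= min_gene_len
  if (!is.null(min_reads_per_codon)) {
    gs <- gene_stats(track, genes, min_reads_per_codon, NULL)
    keep <- keep & genes$gene_id %in% gs$retained
  }
  genes <- genes[keep, , drop = FALSE]
  if (!nrow(genes)) stop("no genes qualify for the metagene")
  rows <- matrix(NA_real_, nrow(genes), length(off))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sgn <- if (g$strand == "+") 1L else -1L
    p <- .anchor_pos(g, anchor) + sgn * off
    if (min(p) < 0L || max(p) >= track$lengths[[g$contig]]) next
    rows[i, ] <- track$counts[[g$contig]][[g$strand]][p + 1L]
  }
  ok <- !is.na(rows[, 1])
  if (normalization == "mean") {
    m <- rowMeans(rows)
    ok <- ok & !is.na(m) & m > 0
    rows <- rows / ifelse(m > 0, m, 1)
  }
  rows <- rows[ok, , drop = FALSE]
  if (!nrow(rows)) stop("no genes qualify for the metagene")
  structure(list(offset = off, mean = colMeans(rows),
                 n_genes = nrow(rows), anchor = toupper(anchor),
                 normalization = normalization),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("<MetageneProfile>", x$anchor, "-anchored, offsets ", min(x$offset),
      "..", max(x$offset), ", ", x$n_genes, " genes (",
      x$normalization, "-normalized)\n", sep = "")
  invisible(x)
}

#' Offset of the maximum of a metagene profile
#'
#' @param profile A `MetageneProfile`.
#' @param search_window Optional `c(lo, hi)` restricting the search.
#' @return The offset (nt) of the maximum average density; ties are broken
#'   toward the smallest offset with a warning.
#' @export
peak_offset <- function(profile, search_window = NULL) {
  off <- profile$offset
  val <- profile$mean
  if (!is.null(search_window)) {
    sel <- off >= search_window[1] & off <= search_window[2]
    if (!any(sel)) stop("empty search window")
    off <- off[sel]; val <- val[sel]
  }
  top <- which(val == max(val))
  if (length(top) > 1L)
    warning("peak_offset: ", length(top),
            " tied maxima; returning the 5'-most")
  off[top[1]]
}

#' Per-gene 5'/3' polarity ratio
#'
#' Ratio of mean per-codon 3'-end density over the first `head_codons`
#' codons to the mean from `tail_from_codon` to the end of the gene. A
#' pseudocount (default 0.5 reads) is added to the tail total to keep ratios
#' finite. Genes too short for both windows are skipped.
#'
#' @param track A `DensityTrack`.
#' @param annotation Annotation.
#' @param head_codons Head window size in codons (default 100).
#' @param tail_from_codon First codon of the tail window (default 151).
#' @param pseudocount Reads added to the tail total.
#' @return List with `per_gene` (data frame `gene_id`, `head_mean`,
#'   `tail_mean`, `ratio`) and `mean` / `median` ratio summaries.
#' @export
polarity_ratio <- function(track, annotation, head_codons = 100L,
                           tail_from_codon = 151L, pseudocount = 0.5) {
  genes <- .ann_genes(annotation)
  n_cod <- (genes$end - genes$start) %/% 3L
  genes <- genes[n_cod > tail_from_codon, , drop = FALSE]
  if (!nrow(genes)) {
    message("polarity_ratio: no gene long enough for both windows")
    return(list(per_gene = data.frame(), mean = NA_real_, median = NA_real_))
  }
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    v <- .gene_vec(track, g)
    per_codon <- colSums(matrix(v, nrow = 3L))
    N <- length(per_codon)
    head_mean <- mean(per_codon[1:head_codons])
    tail_mean <- (sum(per_codon[tail_from_codon:N]) + pseudocount) /
      (N - tail_from_codon + 1L)
    data.frame(gene_id = g$gene_id, head_mean = head_mean,
               tail_mean = tail_mean, ratio = head_mean / tail_mean,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, res)
  list(per_gene = per_gene, mean = mean(per_gene$ratio),
       median = median(per_gene$ratio))
}

#' Write a density track as BedGraph (one file per strand)
#'
#' @param track A `DensityTrack`.
#' @param prefix Output path prefix; files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written.
#' @return Invisibly, the two file paths.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c(paste0(prefix, "_plus.bedGraph"),
             paste0(prefix, "_minus.bedGraph"))
  for (si in 1:2) {
    st <- c("+", "-")[si]
    grl <- lapply(names(track$counts), function(ctg) {
      v <- track$counts[[ctg]][[st]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0L
      if (!any(keep)) return(NULL)
      GenomicRanges::GRanges(ctg,
        IRanges::IRanges(start = starts[keep], end = ends[keep]),
        score = r$values[keep])
    })
    gr <- do.call(c, c(grl[!vapply(grl, is.null, TRUE)], list()))
    if (is.null(gr))
      gr <- GenomicRanges::GRanges(score = numeric(0))
    rtracklayer::export(gr, paths[si], format = "bedGraph")
  }
  invisible(paths)
}
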