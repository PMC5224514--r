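# Sub-codon reading-frame analysis: frame fractions, A-site attribution of
# 3' ends, per-codon cleavage heatmap, the NNC shift correction, and
# programmed-frameshift detection by multinomial change-point segmentation.
#
# Sub-codon positions are numbered 1/2/3 = offsets 0/1/2 within a codon
# (position 2 is the codon's second nucleotide).

# CDS sequence (transcript orientation) from genome + gene coordinates
.cds_seq_genome <- function(genome, g) {
  if (inherits(genome, "SyntheticTranscriptome")) genome <- genome$genome
  s <- as.character(Biostrings::subseq(genome[[g$contig]], g$start + 1L,
                                       g$end))
  if (g$strand == "-") s <- .revcomp(s)
  s
}

#' Sub-codon position fractions of 3'-end density
#'
#' Maps every 3'-end position in the chosen region to sub-codon position
#' 1, 2 or 3 of its codon in the gene's annotated frame and returns the
#' density fractions. All genes are included without a coverage threshold,
#' but reads within the first and final `exclude_end_nt` nt of each ORF are
#' excluded (region `"cds_interior"`). Region `"utr3"` instead uses the
#' `utr3_len` nt downstream of each stop codon (truncated at the next
#' annotated gene or contig end), with the reading frame carried over from
#' the preceding ORF.
#'
#' @param track A `DensityTrack`.
#' @param annotation Annotation.
#' @param exclude_end_nt nt excluded at each ORF end (default 30).
#' @param region `"cds_interior"` or `"utr3"`.
#' @param utr3_len Length (nt) of the 3'-UTR window (default 90).
#' @return Object of class `FrameSummary`: list with `fraction` (f1, f2,
#'   f3), `counts`, `n_reads`, `region`; fractions are `NA` (flagged) when
#'   the region holds no reads.
#' @export
subcodon_fractions <- function(track, annotation, exclude_end_nt = 30L,
                               region = c("cds_interior", "utr3"),
                               utr3_len = 90L) {
  region <- match.arg(region)
  genes <- .ann_genes(annotation)
  counts <- c(0, 0, 0)
  if (region == "cds_interior") {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      v <- .gene_vec(track, g)
      L <- length(v)
      if (L <= 2L * exclude_end_nt) next
      off <- (exclude_end_nt):(L - exclude_end_nt - 1L)   # 0-based offsets
      sub <- off %% 3L + 1L
      vv <- v[off + 1L]
      counts <- counts + vapply(1:3, function(p) sum(vv[sub == p]), 0)
    }
  } else {
    # mask of annotated positions, per contig, to truncate UTR windows
    ingene <- lapply(track$lengths, function(L) logical(L))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      ingene[[g$contig]][(g$start + 1L):g$end] <- TRUE
    }
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      L <- track$lengths[[g$contig]]
      k <- 0:(utr3_len - 1L)
      pos <- if (g$strand == "+") g$end + k else g$start - 1L - k
      pos <- pos[pos >= 0L & pos < L]
      if (!length(pos)) next
      hit <- ingene[[g$contig]][pos + 1L]
      if (any(hit)) pos <- pos[seq_len(which(hit)[1] - 1L)]
      if (!length(pos)) next
      # frame carried over: CDS length is a multiple of 3
      sub <- (seq_along(pos) - 1L) %% 3L + 1L
      vv <- track$counts[[g$contig]][[g$strand]][pos + 1L]
      counts <- counts + vapply(1:3, function(p) sum(vv[sub == p]), 0)
    }
  }
  n <- sum(counts)
  structure(list(fraction = if (n > 0) counts / n else rep(NA_real_, 3),
                 counts = counts, n_reads = n, region = region),
            class = "FrameSummary")
}

#' @export
print.FrameSummary <- function(x, ...) {
  cat("<FrameSummary>", x$region, "-", x$n_reads, "reads; fractions",
      paste(sprintf("%.3f", x$fraction), collapse = "/"), "\n")
  invisible(x)
}

#' A-site codon from a footprint 3' end
#'
#' Inverts the nuclease geometry: for a RelE library a 3' end at sub-codon
#' position 2 marks cleavage after the 2nd nt of the A-site codon (A-site
#' first nt = end - 1); an end at position 3 is an NNC cut (A-site first nt
#' = end - 2) when the codon ends in C and is flagged ambiguous otherwise;
#' an end at position 1 is taken as a cut after the codon's 1st nt. For an
#' MNase library the A-site first nt is `delta_mnase` (12) nt upstream of
#' the end; ends up to 12 nt past the stop codon resolve to the stop.
#'
#' @param end_pos Genomic 3'-end position(s), 0-based.
#' @param gene One-row gene data frame.
#' @param library_type "rele" or "mnase".
#' @param genome Genome (needed for the NNC rule in RelE libraries).
#' @param delta_mnase MNase boundary offset (default 12).
#' @return Data frame with `codon` (1-based index, NA when unresolvable),
#'   `subpos`, and `ambiguous`.
#' @export
asite_codon_from_3prime <- function(end_pos, gene, library_type = "rele",
                                    genome = NULL, delta_mnase = 12L) {
  g <- gene
  L <- g$end - g$start
  off <- if (g$strand == "+") end_pos - g$start else g$end - 1L - end_pos
  if (library_type == "mnase") {
    a_first <- off - delta_mnase
    codon <- ifelse(a_first >= 0L & a_first < L, a_first %/% 3L + 1L,
                    NA_integer_)
    return(data.frame(codon = as.integer(codon),
                      subpos = as.integer(off %% 3L + 1L),
                      ambiguous = is.na(codon)))
  }
  if (is.null(genome)) stop("genome is required for RelE A-site attribution")
  cds <- .cds_seq_genome(genome, g)
  sub <- off %% 3L + 1L
  codon <- off %/% 3L + 1L
  codon[off < 0L | off >= L] <- NA_integer_
  third_nt <- substr(rep(cds, length(off)), codon * 3L, codon * 3L)
  ambiguous <- !is.na(codon) & sub == 3L & third_nt != "C"
  codon[ambiguous] <- NA_integer_
  data.frame(codon = as.integer(codon), subpos = as.integer(sub),
             ambiguous = ambiguous | is.na(codon))
}

#' Per-codon sub-codon cleavage heatmap
#'
#' Attributes RelE-library 3' ends to A-site codons and tabulates occupancy
#' over the 61 sense codons by sub-codon cut position. Ambiguous ends
#' (position-3 ends on non-NNC codons) are dropped and their fraction
#' reported. Rows are normalized to sum to 1; rows with fewer than
#' `min_reads` reads are flagged.
#'
#' @param track A `DensityTrack` (RelE library).
#' @param annotation Annotation.
#' @param genome Genome.
#' @param min_reads Row flagging threshold (default 50).
#' @return Object of class `CodonHeatmap`: `fraction` (61 x 3 matrix),
#'   `counts`, `flagged` (rows below `min_reads`), `ambiguous_fraction`.
#' @export
codon_heatmap <- function(track, annotation, genome, min_reads = 50L) {
  genes <- .ann_genes(annotation)
  sc <- sense_codons()
  counts <- matrix(0, length(sc), 3, dimnames = list(sc, paste0("p", 1:3)))
  n_amb <- 0
  n_tot <- 0
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- .gene_vec(track, g)
    cds <- .cds_seq_genome(genome, g)
    L <- length(v)
    off <- which(v > 0L) - 1L
    if (!length(off)) next
    w <- v[off + 1L]
    sub <- off %% 3L + 1L
    codon_idx <- off %/% 3L + 1L
    cod <- substr(rep(cds, length(off)), 3L * codon_idx - 2L,
                  3L * codon_idx)
    amb <- sub == 3L & substr(cod, 3L, 3L) != "C"
    n_tot <- n_tot + sum(w)
    n_amb <- n_amb + sum(w[amb])
    ok <- !amb & cod %in% sc
    for (p in 1:3) {
      sel <- ok & sub == p
      if (any(sel))
        counts[, p] <- counts[, p] +
          vapply(split(w[sel], factor(cod[sel], levels = sc)), sum, 0)
    }
  }
  rs <- rowSums(counts)
  frac <- counts / ifelse(rs > 0, rs, 1)
  frac[rs == 0, ] <- NA_real_
  structure(list(fraction = frac, counts = counts,
                 flagged = rownames(counts)[rs < min_reads],
                 ambiguous_fraction = if (n_tot > 0) n_amb / n_tot else NA),
            class = "CodonHeatmap")
}

#' @export
print.CodonHeatmap <- function(x, ...) {
  cat("<CodonHeatmap> 61 sense codons x 3 sub-codon positions;",
      length(x$flagged), "row(s) flagged;",
      sprintf("%.1f%%", 100 * x$ambiguous_fraction), "ends ambiguous\n")
  invisible(x)
}

#' NNC shift correction
#'
#' RelE preferentially cleaves codons ending in C after their third
#' nucleotide rather than the second. This correction moves, for every CDS
#' codon ending in C, the 3'-end density at the codon's 3rd nucleotide to
#' its 2nd nucleotide. All other positions are untouched and total density
#' is conserved exactly.
#'
#' @param track A `DensityTrack`.
#' @param annotation Annotation.
#' @param genome Genome.
#' @return The corrected `DensityTrack`.
#' @export
nnc_shift <- function(track, annotation, genome) {
  genes <- .ann_genes(annotation)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- .gene_vec(track, g)
    cds <- .cds_seq_genome(genome, g)
    ncod <- length(v) %/% 3L
    third <- substr(rep(cds, ncod), 3L * (1:ncod), 3L * (1:ncod))
    nnc <- which(third == "C")
    if (length(nnc)) {
      p3 <- 3L * nnc
      v[p3 - 1L] <- v[p3 - 1L] + v[p3]
      v[p3] <- 0L
      track <- .set_gene_vec(track, g, v)
    }
  }
  track
}

# Frameshift calls require the alternative to beat the best single-frame
# model by this likelihood-ratio margin. Max-score distributions on no-shift
# simulations are bounded near 0 (the alternative's extra parameters buy
# almost nothing under the null; see the methods vignette), while genuine
# shifts score in the hundreds; 10 keeps a wide safety margin over the
# calibrated 99th percentile.
.FS_THRESHOLD <- 10

# Expected RelE cut-end intensity per gene position for ribosomes decoding
# in frame offset r (0 = annotated, 1 = +1, 2 = -1), from the nuclease
# model: regular cuts after the 2nd nt of the A-site codon, NNC codons cut
# after the 3rd with prob p_nnc, context retention weights for C at -1 and
# G at +1 of the cut. Assumes uniform A-site occupancy within a frame.
.lam_frame <- function(chars, r, nucl) {
  L <- length(chars)
  lam <- numeric(L)
  wts <- function(e)  # e is the 1-based index of the cut's -1 nt
    ((chars[e] == "C") * (nucl$w_minus1_C - 1) + 1) *
      ifelse(e + 1 <= L, (chars[e + 1] == "G") * (nucl$w_plus1_G - 1) + 1, 1)
  a <- seq(r, L - 3, by = 3)                 # 0-based A-site first nts
  nnc <- chars[a + 3] == "C"
  e_reg <- a + nucl$delta_rele               # 0-based end offsets
  e_nnc <- a + 2
  lam[e_reg + 1] <- lam[e_reg + 1] +
    ifelse(nnc, 1 - nucl$p_nnc, 1) * wts(e_reg + 1)
  lam[e_nnc + 1] <- lam[e_nnc + 1] + nnc * nucl$p_nnc * wts(e_nnc + 1)
  lam
}

#' Scan a gene for a reading-frame change point
#'
#' Binary segmentation of the gene's 3'-end density with a multinomial
#' likelihood-ratio score: for every candidate shift codon m, the expected
#' cut-position profile is annotated-frame RelE cleavage up to codon m and
#' +1-frame (or -1-frame) cleavage after it, with per-position emission
#' probabilities derived from the nuclease model (cut after the 2nd nt,
#' NNC codons after the 3rd, -1 C / +1 G retention weights) plus a small
#' uniform mis-cleavage floor. The reported score is twice the
#' log-likelihood margin of the best split over the best single-frame
#' model; a call is emitted when it exceeds `threshold`. Sequence-aware
#' emission probabilities make the scan robust to the frame ambiguity of
#' cuts following C (which the plain sub-codon composition is blind to),
#' so the NNC shift correction need not be applied beforehand.
#'
#' @param track A `DensityTrack` (raw RelE library).
#' @param gene One-row gene data frame (or a gene id with `annotation`).
#' @param annotation Annotation (needed when `gene` is an id).
#' @param genome Genome providing the gene sequence.
#' @param nuclease RelE [nuclease_model()] whose parameters define the
#'   expected cut profile.
#' @param min_reads Minimum 3'-end count in the gene (default 50).
#' @param threshold Likelihood-ratio score threshold (default frozen from
#'   no-shift calibration).
#' @param min_seg Minimum segment length in codons.
#' @param eps Uniform mis-cleavage floor mixed into the expected profile.
#' @return A one-row data frame (`gene_id`, `codon` = shift codon = last
#'   codon decoded in the annotated frame, `frame_before`, `frame_after`
#'   (dominant sub-codon cut positions implied by the frames),
#'   `direction` ("+1"/"-1"), `score`), or `NULL` when no change point is
#'   supported.
#' @export
frameshift_scan <- function(track, gene, annotation = NULL, genome = NULL,
                            nuclease = nuclease_model("RELE"),
                            min_reads = 50L, threshold = .FS_THRESHOLD,
                            min_seg = 3L, eps = 0.02) {
  if (is.character(gene)) {
    genes <- .ann_genes(annotation)
    gene <- genes[match(gene, genes$gene_id), , drop = FALSE]
  }
  g <- gene
  if (is.null(genome)) stop("genome is required")
  v <- as.numeric(.gene_vec(track, g))
  L <- length(v)
  N <- L %/% 3L
  if (sum(v) < min_reads) {
    message("frameshift_scan: ", g$gene_id, " has ", sum(v),
            " reads (< ", min_reads, "); no scan")
    return(NULL)
  }
  if (N < 2L * min_seg + 1L) return(NULL)
  chars <- strsplit(.cds_seq_genome(genome, g), "")[[1]]
  lam <- lapply(0:2, function(r) .lam_frame(chars, r, nuclease))
  nz <- which(v > 0)
  vn <- v[nz]
  ll_of <- function(lam_nz, S)
    sum(vn * log((1 - eps) * lam_nz / S + eps / L))
  ll_null <- max(vapply(lam, function(l) ll_of(l[nz], sum(l)), 0))
  cums <- lapply(lam, cumsum)
  best <- list(ll = -Inf)
  for (dir in 1:2) {                 # 1 = +1 frame after, 2 = -1 frame
    la <- lam[[dir + 1L]]
    ca <- cums[[dir + 1L]]
    for (m in min_seg:(N - min_seg)) {
      b <- 3L * m
      S <- cums[[1]][b] + ca[L] - ca[b]
      if (S <= 0) next
      lam_nz <- ifelse(nz <= b, lam[[1]][nz], la[nz])
      cur <- ll_of(lam_nz, S)
      if (cur > best$ll) best <- list(ll = cur, m = m, dir = dir)
    }
  }
  score <- 2 * (best$ll - ll_null)
  if (!is.finite(score) || score < threshold) return(NULL)
  data.frame(gene_id = g$gene_id, codon = best$m,
             frame_before = 2L, frame_after = c(3L, 1L)[best$dir],
             direction = c("+1", "-1")[best$dir],
             score = score, stringsAsFactors = FALSE)
}
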