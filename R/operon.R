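# Operon 5'-polarity analysis: single-transcription-unit filtering, per-gene
# treated/control density ratios binned by operon position, and a
# Mann-Whitney (Wilcoxon rank-sum) test.

#' Filter operon genes to single, uniformly expressed transcription units
#'
#' Implements the operon filters used for position-ratio analysis:
#' monocistronic genes are excluded; a polycistronic operon is excluded when
#' its per-gene RNA-seq density varies by more than `max_fold` (strict
#' inequality) between its most and least covered genes, since such operons
#' probably contain multiple transcription units; and genes below `min_rpkm`
#' in the RNA-seq track or any supplied Ribo-seq track are excluded.
#'
#' @param annotation Annotation with operon assignments.
#' @param rnaseq_track RNA-seq `DensityTrack`.
#' @param ribo_tracks Optional list of Ribo-seq `DensityTrack`s that genes
#'   must also pass the rpkm floor in.
#' @param max_fold Maximum allowed max/min per-gene RNA density within an
#'   operon (default 5).
#' @param min_rpkm Expression floor (default 1).
#' @param stat Per-gene density summary used for the fold filter: mean
#'   (default) or median per-nt density over the CDS.
#' @return Data frame of surviving genes (with `operon_id`,
#'   `operon_position`); excluded operons/genes are reported via messages.
#' @export
define_single_TUs <- function(annotation, rnaseq_track, ribo_tracks = NULL,
                              max_fold = 5, min_rpkm = 1,
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  genes <- .ann_genes(annotation)
  poly_ids <- names(which(table(genes$operon_id) >= 2L))
  mono <- is.na(genes$operon_id) | !(genes$operon_id %in% poly_ids)
  if (any(mono))
    message("define_single_TUs: excluding ", sum(mono),
            " monocistronic gene(s)")
  genes <- genes[!mono, , drop = FALSE]
  if (!nrow(genes)) return(genes)
  dens <- vapply(seq_len(nrow(genes)), function(i) {
    v <- .gene_vec(rnaseq_track, genes[i, ])
    if (stat == "mean") mean(v) else median(as.numeric(v))
  }, 0)
  fold <- vapply(split(dens, genes$operon_id), function(d) {
    if (min(d) <= 0) Inf else max(d) / min(d)
  }, 0)
  drop_op <- names(fold)[fold > max_fold]
  if (length(drop_op))
    message("define_single_TUs: excluding ", length(drop_op),
            " operon(s) with RNA-seq density varying > ", max_fold, "-fold")
  genes <- genes[!genes$operon_id %in% drop_op, , drop = FALSE]
  if (!is.null(min_rpkm) && nrow(genes)) {
    tracks <- c(list(rnaseq_track), if (is.null(ribo_tracks)) list()
                else ribo_tracks)
    ok <- rep(TRUE, nrow(genes))
    for (tr in tracks) {
      gs <- gene_stats(tr, genes, min_reads_per_codon = NULL,
                       min_rpkm = min_rpkm)
      ok <- ok & genes$gene_id %in% gs$retained
    }
    if (any(!ok))
      message("define_single_TUs: excluding ", sum(!ok),
              " gene(s) below ", min_rpkm, " rpkm")
    genes <- genes[ok, , drop = FALSE]
  }
  rownames(genes) <- NULL
  genes
}

#' Per-gene treated/control density ratios by operon position
#'
#' For each gene surviving [define_single_TUs()], computes the ratio of
#' mean per-nt 3'-end density in the treated track over the control track
#' (each normalized to its library total, so ratios are comparable across
#' libraries of different depth), and bins genes by their position in the
#' operon (1, 2, 3, 4, >=5). Genes with zero control density are excluded
#' with a message.
#'
#' @param treated_track,control_track `DensityTrack`s (e.g. RelE-treated
#'   Ribo-seq vs wild-type Ribo-seq).
#' @param tu_genes Gene data frame from [define_single_TUs()].
#' @param rna_tracks Optional `list(treated =, control =)` of RNA-seq tracks
#'   to fill a parallel `rna_ratio` column.
#' @return Data frame: `gene_id`, `operon_id`, `position`, `bin` (factor
#'   "1","2","3","4",">=5"), `ratio`, optional `rna_ratio`.
#' @export
position_ratios <- function(treated_track, control_track, tu_genes,
                            rna_tracks = NULL) {
  if (!nrow(tu_genes)) stop("tu_genes is empty")
  per_nt <- function(track, g)
    mean(.gene_vec(track, g)) / max(track$total, 1L) * 1e6
  tr <- vapply(seq_len(nrow(tu_genes)), function(i)
    per_nt(treated_track, tu_genes[i, ]), 0)
  ct <- vapply(seq_len(nrow(tu_genes)), function(i)
    per_nt(control_track, tu_genes[i, ]), 0)
  ok <- ct > 0
  if (any(!ok))
    message("position_ratios: excluding ", sum(!ok),
            " gene(s) with zero control density")
  out <- data.frame(gene_id = tu_genes$gene_id,
                    operon_id = tu_genes$operon_id,
                    position = tu_genes$operon_position,
                    ratio = tr / ifelse(ok, ct, NA_real_),
                    stringsAsFactors = FALSE)
  if (!is.null(rna_tracks)) {
    rt <- vapply(seq_len(nrow(tu_genes)), function(i)
      per_nt(rna_tracks$treated, tu_genes[i, ]), 0)
    rc <- vapply(seq_len(nrow(tu_genes)), function(i)
      per_nt(rna_tracks$control, tu_genes[i, ]), 0)
    out$rna_ratio <- ifelse(rc > 0, rt / rc, NA_real_)
  }
  out <- out[ok, , drop = FALSE]
  out$bin <- factor(ifelse(out$position >= 5L, ">=5",
                           as.character(out$position)),
                    levels = c("1", "2", "3", "4", ">=5"))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Wilcoxon/Mann-Whitney test with midranks for ties. For
#' `length(a) + length(b) <= 12` the null distribution of U is enumerated
#' exactly over all group assignments of the observed midranks; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `U` (statistic for sample `a`), `p_value` (two-sided),
#'   `method`, `n_a`, `n_b`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))                       # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n <= 12L) {
    # exact two-sided: mass at least as far from the null mean as observed
    # (U is symmetric about n_a*n_b/2, also under midranks)
    idx <- combn(n, n_a)
    Us <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    mu <- n_a * n_b / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal-approximation"
  }
  list(U = U, p_value = min(p, 1), method = method, n_a = n_a, n_b = n_b)
}
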