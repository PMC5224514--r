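# Nuclease digestion of ribosome snapshots into footprints, SAM emission,
# and the uniform alkaline-hydrolysis RNA-seq fragment model.

# Reposition MNase cuts for A/T preference. `pos` are candidate boundary
# positions (0-based transcript offsets of the nt just 5' of the cut for the
# 3' boundary, or of the footprint's first nt for the 5' boundary);
# `target_at[i]` says whether read i's realized cut should sit before an A/T.
# `probe_shift` is the offset from the boundary position to the nt examined
# (+1 for the 3' boundary: first nt after the cut; 0 for the 5' boundary).
.reposition_at <- function(tustr, pos, target_at, probe_shift, max_shift = 3L) {
  out <- pos
  done <- rep(FALSE, length(pos))
  for (s in c(0L, as.vector(rbind(-seq_len(max_shift), seq_len(max_shift))))) {
    if (all(done)) break
    cand <- pos + s
    nt <- substr(tustr, cand + probe_shift + 1L, cand + probe_shift + 1L)
    ok <- !done & (nt %in% c("A", "T")) == target_at & nt != ""
    out[ok] <- cand[ok]
    done <- done | ok
  }
  out
}

#' Digest a ribosome snapshot into footprints
#'
#' Converts each ribosome of a snapshot into an aligned footprint according
#' to the library's nuclease geometry. The 5' end always follows the MNase
#' model (`delta_mnase5` upstream of the A-site codon, A/T cut preference).
#' The 3' end depends on `library_type`:
#' \describe{
#'   \item{"rele"}{RelE cleaves after the 2nd nt of the A-site codon
#'     (`delta_rele`); NNC codons are cut after their 3rd nt with probability
#'     `p_nnc`. The -1 C / +1 G sequence preference is applied by
#'     acceptance-rejection thinning (footprints whose cut context is
#'     disfavoured are less likely to be sampled into the library), so the
#'     A-site geometry of surviving reads is exact. Ribosomes with occupied
#'     A sites block RelE with probability `p_block_occupied` and yield
#'     MNase-geometry 3' ends instead.}
#'   \item{"mnase"}{All 3' ends at the MNase ribosome boundary
#'     (`delta_mnase` downstream of the A-site codon first nt, with jitter
#'     and A/T preference).}
#' }
#' Footprints running past a transcript end are truncated there and flagged.
#'
#' @param snapshot Snapshot data frame from [place_ribosomes()] or
#'   [simulate_dynamics()].
#' @param tx The `SyntheticTranscriptome` the snapshot was drawn on.
#' @param library_type "rele" or "mnase".
#' @param rele,mnase [nuclease_model()] objects for the two enzymes.
#' @param seed Optional integer seed.
#' @return A footprint data frame: genomic `contig`/`strand`, orientation-
#'   aware `five_pos`/`three_pos` (0-based, inclusive), leftmost-based
#'   `start`/`end` (0-based half-open), `length`, `nuclease` tag of the 3'
#'   end, source `gene_id`, A-site codon index `a_codon` (1-based,
#'   annotated frame) and offset `a_off`, and a `truncated` flag.
#' @export
digest <- function(snapshot, tx, library_type = c("rele", "mnase"),
                   rele = nuclease_model("RELE"),
                   mnase = nuclease_model("MNASE"),
                   seed = NULL) {
  stopifnot(inherits(tx, "SyntheticTranscriptome"))
  library_type <- match.arg(library_type)
  .stopifnot_cols(snapshot, c("tu_id", "gene_id", "a_off"), "snapshot")
  if (!nrow(snapshot)) stop("empty snapshot")
  .with_seed(seed, {
    n <- nrow(snapshot)
    gi <- match(snapshot$gene_id, tx$genes$gene_id)
    ki <- match(snapshot$tu_id, tx$tus$tu_id)
    tustr <- tx$tx_seq[snapshot$tu_id]
    tu_len <- tx$tus$length[ki]
    a_tx <- tx$genes$tx_offset[gi] + snapshot$a_off
    occupied <- if (!is.null(snapshot$occupied)) snapshot$occupied
                else rep(FALSE, n)

    jit <- function(sd) if (sd > 0) as.integer(round(rnorm(n, 0, sd)))
                        else integer(n)

    # --- 3' end ---
    if (library_type == "rele") {
      blocked <- occupied & (runif(n) < rele$p_block_occupied)
      a_codon_seq <- substr(tustr, a_tx + 1L, a_tx + 3L)
      nnc <- substr(a_codon_seq, 3L, 3L) == "C" & runif(n) < rele$p_nnc
      t3 <- a_tx + ifelse(nnc, 2L, rele$delta_rele)
      if (rele$p_miscleave > 0) {
        mis <- runif(n) < rele$p_miscleave
        t3[mis] <- a_tx[mis] + .sample_int(3L, sum(mis)) - 1L
      }
      nucl <- rep("RELE", n)
      # occupied A sites are protected; MNase trims to the ribosome boundary
      if (any(blocked)) {
        t3b <- a_tx[blocked] + mnase$delta_mnase + jit(mnase$boundary_jitter_sd)[blocked]
        if (!is.na(mnase$p_cut_before_AT)) {
          at <- runif(sum(blocked)) < mnase$p_cut_before_AT
          t3b <- .reposition_at(tustr[blocked], t3b, at, probe_shift = 1L)
        }
        t3[blocked] <- t3b
        nucl[blocked] <- "MNASE"
      }
    } else {
      t3 <- a_tx + mnase$delta_mnase + jit(mnase$boundary_jitter_sd)
      if (!is.na(mnase$p_cut_before_AT)) {
        at <- runif(n) < mnase$p_cut_before_AT
        t3 <- .reposition_at(tustr, t3, at, probe_shift = 1L)
      }
      nucl <- rep("MNASE", n)
    }

    # --- 5' end: always MNase ---
    t5 <- a_tx - mnase$delta_mnase5 + jit(mnase$boundary_jitter_sd)
    if (!is.na(mnase$p_cut_before_AT)) {
      at5 <- runif(n) < mnase$p_cut_before_AT
      t5 <- .reposition_at(tustr, t5, at5, probe_shift = 0L)
    }

    truncated <- t5 < 0L | t3 > tu_len - 1L
    t5 <- pmax(t5, 0L)
    t3 <- pmin(t3, tu_len - 1L)

    keep <- rep(TRUE, n)
    if (library_type == "rele") {
      # acceptance-rejection thinning for the -1 C / +1 G preference
      is_rele <- nucl == "RELE"
      w <- rep(1, n)
      m1 <- substr(tustr, t3 + 1L, t3 + 1L)   # -1 of the cut = last footprint nt
      p1 <- substr(tustr, t3 + 2L, t3 + 2L)   # +1 of the cut
      w[is_rele & m1 == "C"] <- w[is_rele & m1 == "C"] * rele$w_minus1_C
      w[is_rele & p1 == "G"] <- w[is_rele & p1 == "G"] * rele$w_plus1_G
      keep <- runif(n) < w / (rele$w_minus1_C * rele$w_plus1_G)
      keep[!is_rele] <- TRUE
    }

    # transcript -> genomic coordinates
    strand <- tx$tus$strand[ki]
    tu_start <- tx$tus$start[ki]
    g5 <- ifelse(strand == "+", tu_start + t5, tu_start + tu_len - 1L - t5)
    g3 <- ifelse(strand == "+", tu_start + t3, tu_start + tu_len - 1L - t3)
    fp <- data.frame(
      read_id = sprintf("fp%07d", seq_len(n)),
      contig = tx$tus$contig[ki], strand = strand,
      five_pos = as.integer(g5), three_pos = as.integer(g3),
      start = as.integer(pmin(g5, g3)), end = as.integer(pmax(g5, g3) + 1L),
      length = as.integer(t3 - t5 + 1L),
      nuclease = nucl, gene_id = snapshot$gene_id,
      a_codon = as.integer(snapshot$a_off %/% 3L + 1L),
      a_off = as.integer(snapshot$a_off),
      occupied = occupied, truncated = truncated,
      stringsAsFactors = FALSE)
    fp[keep & fp$length >= 1L, , drop = FALSE]
  })
}

#' Write footprints to SAM (and optionally FASTQ)
#'
#' Footprints with lengths outside `window` are dropped, as are truncated
#' footprints when `drop_truncated`. SAM records are single-end, ungapped
#' (`<len>M`), with flag 16 and forward-strand sequence for reverse-strand
#' footprints, and 1-based leftmost coordinates per the SAM standard.
#'
#' @param footprints Footprint data frame from [digest()] or
#'   [simulate_rnaseq()].
#' @param genome A [Biostrings::DNAStringSet] (or a `SyntheticTranscriptome`,
#'   whose genome is used).
#' @param sam_path Output SAM path.
#' @param window Length window `c(min, max)`, inclusive.
#' @param drop_truncated Drop footprints flagged as truncated.
#' @param fastq_path Optional FASTQ output (original read orientation).
#' @param truth_path Optional TSV with per-read ground truth (gene, A-site
#'   codon, nuclease tag) for the emitted reads.
#' @return The number of emitted records.
#' @export
emit_reads <- function(footprints, genome, sam_path,
                       window = c(20L, 40L), drop_truncated = TRUE,
                       fastq_path = NULL, truth_path = NULL) {
  if (inherits(genome, "SyntheticTranscriptome")) genome <- genome$genome
  if (window[1] > window[2]) stop("window must satisfy min <= max")
  fp <- footprints[footprints$length >= window[1] &
                   footprints$length <= window[2], , drop = FALSE]
  if (drop_truncated && nrow(fp)) fp <- fp[!fp$truncated, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  if (nrow(fp)) {
    fwd <- as.character(Biostrings::subseq(
      genome[fp$contig], start = fp$start + 1L, end = fp$end))
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                   fp$read_id, ifelse(fp$strand == "+", 0L, 16L),
                   fp$contig, fp$start + 1L, fp$length, fwd)
  } else rec <- character(0)
  writeLines(c(hdr, rec), sam_path)
  if (!is.null(fastq_path)) {
    orig <- if (nrow(fp)) ifelse(fp$strand == "+", fwd, .revcomp(fwd))
            else character(0)
    writeLines(as.vector(rbind(paste0("@", fp$read_id), orig, "+",
                               strrep("I", nchar(orig)))), fastq_path)
  }
  if (!is.null(truth_path))
    write.table(fp[, c("read_id", "gene_id", "a_codon", "a_off", "nuclease",
                       "strand", "five_pos", "three_pos")],
                truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(fp)
}

#' Simulate an alkaline-hydrolysis RNA-seq library
#'
#' Fragments each transcription unit uniformly: fragment start positions are
#' uniform over the transcript, lengths uniform in `fragment_window`, with no
#' sequence bias at either fragment end. Expected per-nt coverage of a
#' transcript is proportional to its abundance.
#'
#' @param tx A `SyntheticTranscriptome`.
#' @param abundance Named numeric vector of relative abundances per gene
#'   (default: all equal). A transcription unit's weight is the mean over its
#'   member genes.
#' @param fragment_window Fragment length window (nt), default 40-60.
#' @param n_reads Number of fragments to draw.
#' @param seed Optional integer seed.
#' @return A footprint-style data frame (nuclease tag "RNASEQ").
#' @export
simulate_rnaseq <- function(tx, abundance = NULL,
                            fragment_window = c(40L, 60L),
                            n_reads = 10000L, seed = NULL) {
  stopifnot(inherits(tx, "SyntheticTranscriptome"))
  g <- tx$genes
  if (is.null(abundance))
    abundance <- setNames(rep(1, nrow(g)), g$gene_id)
  if (any(abundance < 0)) stop("abundances must be >= 0")
  tu_ab <- vapply(split(abundance[g$gene_id], g$tu_id), mean, 0)
  if (sum(tu_ab) <= 0) stop("all abundances are zero")
  .with_seed(seed, {
    ki <- match(names(tu_ab), tx$tus$tu_id)
    len <- tx$tus$length[ki]
    w <- tu_ab * len                        # coverage proportional to abundance
    pick <- .sample_int(length(tu_ab), n_reads, prob = w / sum(w))
    flen <- .sample_int(fragment_window[2] - fragment_window[1] + 1L,
                        n_reads) + fragment_window[1] - 1L
    tulen <- len[pick]
    flen <- pmin(flen, tulen)
    t5 <- floor(runif(n_reads) * (tulen - flen + 1L))
    t3 <- t5 + flen - 1L
    strand <- tx$tus$strand[ki][pick]
    tu_start <- tx$tus$start[ki][pick]
    g5 <- ifelse(strand == "+", tu_start + t5, tu_start + tulen - 1L - t5)
    g3 <- ifelse(strand == "+", tu_start + t3, tu_start + tulen - 1L - t3)
    data.frame(
      read_id = sprintf("rna%07d", seq_len(n_reads)),
      contig = tx$tus$contig[ki][pick], strand = strand,
      five_pos = as.integer(g5), three_pos = as.integer(g3),
      start = as.integer(pmin(g5, g3)), end = as.integer(pmax(g5, g3) + 1L),
      length = as.integer(flen),
      nuclease = "RNASEQ", gene_id = NA_character_,
      a_codon = NA_integer_, a_off = NA_integer_,
      occupied = FALSE, truncated = FALSE,
      stringsAsFactors = FALSE)
  })
}
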