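# Shared internal helpers: coordinate conventions and codon tables.
#
# All internal coordinates are 0-based half-open [start, end) on the genome.
# "Transcript offsets" are 0-based distances from the 5' end of a transcript
# (or from the first nucleotide of a CDS), in transcript orientation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 61 sense codons
#' @return Character vector of the 61 sense codons (DNA alphabet).
#' @export
sense_codons <- function() {
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  sort(setdiff(all, STOP_CODONS))
}

# uniform codon usage over the 61 sense codons
.uniform_codon_usage <- function() {
  sc <- sense_codons()
  setNames(rep(1 / length(sc), length(sc)), sc)
}

.check_codon_usage <- function(usage) {
  sc <- sense_codons()
  if (is.null(usage)) return(.uniform_codon_usage())
  if (!all(names(usage) %in% sc))
    stop("codon usage table contains stop or invalid codons: ",
         paste(setdiff(names(usage), sc), collapse = ", "))
  usage <- usage[usage > 0]
  full <- setNames(numeric(length(sc)), sc)
  full[names(usage)] <- usage
  if (abs(sum(full) - 1) > 1e-6) full <- full / sum(full)
  full
}

# local, restorable seeding; no-op when seed is NULL
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

.sample_int <- function(n, size, replace = TRUE, prob = NULL) {
  # sample.int without the n==1 surprise of sample()
  sample.int(n, size, replace = replace, prob = prob)
}

# random nucleotide string
.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @keywords internal
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring of a named transcript sequence vector, vectorized over rows
.tx_nt <- function(tx_seq, tu_id, pos) {
  # pos is a 0-based offset; returns "" for out-of-range
  substr(tx_seq[tu_id], pos + 1, pos + 1)
}

.stopifnot_cols <- function(df, cols, what = "data frame") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
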