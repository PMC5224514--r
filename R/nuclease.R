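#' Nuclease digestion model
#'
#' Parameterizes how a nuclease converts a ribosome's A-site position into a
#' footprint boundary.
#'
#' Two models are supported:
#' \describe{
#'   \item{RELE}{RelE is a ribosome-dependent endonuclease that cleaves mRNA
#'     in the A site, after the second nucleotide of the A-site codon
#'     (`delta_rele = 1`: the footprint's 3'-most nucleotide sits 1 nt past
#'     the first nucleotide of the A-site codon). Codons ending in C ("NNC"
#'     codons) are instead cut after their third nucleotide with probability
#'     `p_nnc`. Cleavage sites with C immediately upstream of the cut or G
#'     immediately downstream are favoured by the multiplicative weights
#'     `w_minus1_C` / `w_plus1_G`; the preference is applied by
#'     acceptance-rejection thinning of footprints so that it biases which
#'     cleavages are sampled without moving the A-site-determined cut.
#'     Ribosomes whose A site is stably occupied (bound tRNA or release
#'     factor) block RelE with probability `p_block_occupied` and are
#'     digested back to the MNase 3' boundary instead.}
#'   \item{MNASE}{Micrococcal nuclease trims unprotected mRNA back to the
#'     ribosome boundaries: the 3' boundary sits `delta_mnase` (default 12)
#'     nt downstream of the first nucleotide of the A-site codon, and the 5'
#'     boundary `delta_mnase5` (default 18) nt upstream of it. MNase cuts
#'     preferentially before A and T residues: with probability
#'     `p_cut_before_AT` a boundary is repositioned to the nearest site
#'     (within +/-2 nt) whose downstream neighbour is A or T. Gaussian
#'     boundary jitter (`boundary_jitter_sd`, rounded to integer nt) models
#'     incomplete trimming.}
#' }
#' In both library types the footprint 5' end is always MNase-generated.
#'
#' @param name "RELE" or "MNASE" (case-insensitive).
#' @param delta_rele Offset (nt) from the A-site codon first nucleotide to the
#'   RelE 3' end for non-NNC codons. Default 1 (cut after the 2nd nt).
#' @param p_nnc Probability that an NNC A-site codon is cut after its 3rd nt.
#' @param w_minus1_C,w_plus1_G Preference weights (> 0) for C at the -1 and G
#'   at the +1 position of the cut.
#' @param p_block_occupied Probability an occupied A site blocks RelE.
#' @param p_miscleave Probability a RelE 3' end is mis-placed uniformly at
#'   one of the three sub-codon offsets of the A-site codon instead of the
#'   geometric site (positional noise floor; default 0).
#' @param delta_mnase Offset (nt) from A-site codon first nt to the MNase 3'
#'   boundary. Default 12.
#' @param delta_mnase5 Offset (nt) from A-site codon first nt back to the
#'   MNase 5' boundary. Default 20 (footprints of 33 nt for MNase, 22 nt for
#'   RelE at default geometry).
#' @param p_cut_before_AT Probability that a realized MNase cut sits
#'   immediately 5' of an A or T (the boundary is repositioned within a few
#'   nt to satisfy the drawn preference). `NA` disables sequence-directed
#'   repositioning entirely, leaving pure boundary geometry.
#' @param boundary_jitter_sd Standard deviation (nt) of integer-rounded
#'   Gaussian jitter on MNase boundaries. Default 0.
#' @return An object of class `NucleaseModel`.
#' @examples
#' nuclease_model("RELE")
#' nuclease_model("MNASE", p_cut_before_AT = 0)
#' @export
nuclease_model <- function(name = c("RELE", "MNASE"),
                           delta_rele = 1L, p_nnc = 1.0,
                           w_minus1_C = 3, w_plus1_G = 3,
                           p_block_occupied = 1.0, p_miscleave = 0,
                           delta_mnase = 12L, delta_mnase5 = 20L,
                           p_cut_before_AT = 0.8,
                           boundary_jitter_sd = 0) {
  name <- toupper(name)
  name <- match.arg(name, c("RELE", "MNASE"))
  probs <- c(p_nnc = p_nnc, p_block_occupied = p_block_occupied,
             p_cut_before_AT = p_cut_before_AT, p_miscleave = p_miscleave)
  probs <- probs[!is.na(probs)]
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (w_minus1_C <= 0 || w_plus1_G <= 0)
    stop("preference weights must be > 0")
  if (boundary_jitter_sd < 0) stop("boundary_jitter_sd must be >= 0")
  structure(list(name = name,
                 delta_rele = as.integer(delta_rele), p_nnc = p_nnc,
                 w_minus1_C = w_minus1_C, w_plus1_G = w_plus1_G,
                 p_block_occupied = p_block_occupied,
                 p_miscleave = p_miscleave,
                 delta_mnase = as.integer(delta_mnase),
                 delta_mnase5 = as.integer(delta_mnase5),
                 p_cut_before_AT = p_cut_before_AT,
                 boundary_jitter_sd = boundary_jitter_sd),
            class = "NucleaseModel")
}

#' @export
print.NucleaseModel <- function(x, ...) {
  cat("<NucleaseModel>", x$name, "\n")
  if (x$name == "RELE")
    cat(sprintf("  delta_rele=%d  p_nnc=%.2f  w(-1 C)=%.1f  w(+1 G)=%.1f  p_block_occupied=%.2f\n",
                x$delta_rele, x$p_nnc, x$w_minus1_C, x$w_plus1_G,
                x$p_block_occupied))
  cat(sprintf("  delta_mnase=%d  delta_mnase5=%d  p_cut_before_AT=%.2f  jitter_sd=%.2f\n",
              x$delta_mnase, x$delta_mnase5, x$p_cut_before_AT,
              x$boundary_jitter_sd))
  invisible(x)
}

#' Ribosome dynamics simulation configuration
#'
#' Kinetic parameters for the stochastic translation / cleavage / rescue /
#' reinitiation model. All rates are per ribosome (or per initiation site)
#' per second. The defaults describe an E. coli-like cell under strong RelE
#' induction: elongation at 15 codons/s, initiation at 0.3/s per ORF,
#' cleavage of an unoccupied A site at 0.1/s (so a ribosome translates on the
#' order of 100-150 codons before being hit), and rescue of a stalled
#' ribosome (tmRNA/ArfA pathways pooled) at 0.05/s.
#'
#' In `IN_VITRO` mode elongation and initiation are frozen (lysate treated
#' with chloramphenicol and digested in vitro): ribosome positions are drawn
#' once from a steady-state-like occupancy (uniform across sense codons, plus
#' initiation/termination complexes) and returned unchanged regardless of
#' `sim_time`.
#'
#' @param mode "IN_VIVO" (full dynamics) or "IN_VITRO" (frozen positions).
#' @param k_init Initiation rate per ORF (1/s), applied when the start region
#'   is intact and the first 10 codons are clear of ribosomes.
#' @param k_elong Elongation rate (codons/s).
#' @param k_cleave RelE cleavage rate of an unoccupied A site (1/s). The cut
#'   truncates the mRNA after the 2nd nt of the A-site codon, stalls the
#'   ribosome, and removes the downstream fragment from the initiable pool.
#' @param k_rescue Rescue rate of stalled ribosomes (1/s).
#' @param n_mrna_copies mRNA copies per transcription unit.
#' @param sim_time Simulated time (s).
#' @param read_length_window Length window (nt) retained at library cloning.
#' @param rng_seed Integer seed (mandatory for reproducibility).
#' @param p_occupied_Asite Fraction of ribosomes whose A site carries a stably
#'   bound factor and is therefore immune to RelE cleavage.
#' @param frac_init Fraction of ribosomes that are initiation complexes
#'   (start codon in P site, codon 2 in A site) in frozen/placement modes.
#' @param frac_term Fraction that are termination complexes (stop codon in
#'   the A site) in frozen/placement modes.
#' @param in_vitro_ribosomes_per_gene Ribosome count per gene used to build
#'   the frozen IN_VITRO occupancy.
#' @return Object of class `RiboSimConfig`.
#' @export
ribosim_config <- function(mode = c("IN_VIVO", "IN_VITRO"),
                           k_init = 0.3, k_elong = 15, k_cleave = 0.1,
                           k_rescue = 0.05,
                           n_mrna_copies = 30L, sim_time = 150,
                           read_length_window = c(20L, 40L),
                           rng_seed = 1L,
                           p_occupied_Asite = 0,
                           frac_init = 0.05, frac_term = 0.05,
                           in_vitro_ribosomes_per_gene = 100L) {
  mode <- match.arg(toupper(mode[1]), c("IN_VIVO", "IN_VITRO"))
  rates <- c(k_init = k_init, k_elong = k_elong, k_cleave = k_cleave,
             k_rescue = k_rescue)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (mode == "IN_VITRO") {
    # frozen positions: no initiation or elongation during digestion
    k_init <- 0
    k_elong <- 0
  }
  if (length(read_length_window) != 2 ||
      read_length_window[1] > read_length_window[2])
    stop("read_length_window must be c(min, max) with min <= max")
  if (p_occupied_Asite < 0 || p_occupied_Asite > 1)
    stop("p_occupied_Asite must be in [0, 1]")
  if (is.null(rng_seed)) stop("rng_seed is mandatory")
  structure(list(mode = mode, k_init = k_init, k_elong = k_elong,
                 k_cleave = k_cleave, k_rescue = k_rescue,
                 n_mrna_copies = as.integer(n_mrna_copies),
                 sim_time = sim_time,
                 read_length_window = as.integer(read_length_window),
                 rng_seed = as.integer(rng_seed),
                 p_occupied_Asite = p_occupied_Asite,
                 frac_init = frac_init, frac_term = frac_term,
                 in_vitro_ribosomes_per_gene =
                   as.integer(in_vitro_ribosomes_per_gene)),
            class = "RiboSimConfig")
}

#' @export
print.RiboSimConfig <- function(x, ...) {
  cat("<RiboSimConfig>", x$mode, "\n")
  cat(sprintf("  k_init=%.3g k_elong=%.3g k_cleave=%.3g k_rescue=%.3g\n",
              x$k_init, x$k_elong, x$k_cleave, x$k_rescue))
  cat(sprintf("  copies=%d sim_time=%.3g window=[%d,%d] seed=%d p_occupied=%.2f\n",
              x$n_mrna_copies, x$sim_time, x$read_length_window[1],
              x$read_length_window[2], x$rng_seed, x$p_occupied_Asite))
  invisible(x)
}
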