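# End-to-end orchestration: a single config drives simulation, density,
# metagene, operon, frame and specificity stages and writes a
# machine-readable summary.

.default_config <- function() {
  list(
    seed = 1L,
    outdir = "releseq_out",
    simulate = list(
      n_genes = 20L, n_operons = 4L, gene_length_range = c(1002L, 1500L),
      frameshift = TRUE, mode = "placement", reads_per_gene = 300L,
      rnaseq_reads = 50000L,
      libraries = c("rele", "mnase")),
    filters = list(
      min_reads_per_codon = 0.1, max_fold = 5, min_rpkm = 1,
      exclude_end_nt = 30L, min_gene_len = 1000L),
    metagene = list(offsets = c(-30L, 45L)),
    windows = list(ribo = c(20L, 40L), rnaseq = c(40L, 60L)))
}

# recursive merge with unknown-key rejection
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes simulation (synthetic transcriptome, ribosome placement or
#' dynamics, digestion into RelE / MNase libraries, uniform RNA-seq),
#' density assignment, metagene peak calling, operon position-ratio
#' analysis, reading-frame quantification with the NNC shift, frameshift
#' scanning, and nuclease specificity profiling. Tabular results are written
#' under `outdir` together with a machine-readable `summary.json`. All
#' randomness derives from the single config seed, so a rerun with the same
#' config reproduces the summary byte for byte.
#'
#' @param config A named list overriding the defaults (unknown keys are
#'   rejected), or the path to a YAML file of such overrides.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  libs <- tolower(cfg$simulate$libraries)
  if (!length(libs)) stop("config error: no libraries configured")
  if (!all(libs %in% c("rele", "mnase")))
    stop("config error: libraries must be 'rele' and/or 'mnase'")
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  message("run_pipeline: parameters = ",
          jsonlite::toJSON(cfg, auto_unbox = TRUE))
  seed <- as.integer(cfg$seed)

  ## simulate
  fs <- if (isTRUE(cfg$simulate$frameshift)) frameshift_spec() else NULL
  tx <- generate_transcriptome(cfg$simulate$n_genes, cfg$simulate$n_operons,
                               gene_length_range =
                                 cfg$simulate$gene_length_range,
                               frameshift = fs, seed = seed)
  write_transcriptome(tx, outdir)
  snap <- switch(cfg$simulate$mode,
    placement = place_ribosomes(tx, cfg$simulate$reads_per_gene,
                                seed = seed + 1L),
    in_vivo = simulate_dynamics(tx, ribosim_config("IN_VIVO",
                                                   rng_seed = seed + 1L)),
    in_vitro = simulate_dynamics(tx, ribosim_config("IN_VITRO",
                                                    rng_seed = seed + 1L)),
    stop("config error: simulate.mode must be placement/in_vivo/in_vitro"))
  fps <- list()
  tracks <- list()
  for (i in seq_along(libs)) {
    fp <- digest(snap, tx, library_type = libs[i], seed = seed + 1L + i)
    fps[[libs[i]]] <- fp
    tracks[[libs[i]]] <- assign_3prime_density(footprints_as_reads(fp), tx,
                                               label = libs[i])
    emit_reads(fp, tx, file.path(outdir, paste0(libs[i], ".sam")),
               window = cfg$windows$ribo,
               truth_path = file.path(outdir,
                                      paste0(libs[i], "_truth.tsv")))
  }
  rna_fp <- simulate_rnaseq(tx, n_reads = cfg$simulate$rnaseq_reads,
                            fragment_window = cfg$windows$rnaseq,
                            seed = seed + 10L)
  rna_track <- assign_3prime_density(footprints_as_reads(rna_fp), tx,
                                     label = "rnaseq")

  summary <- list(seed = seed, libraries = libs)

  ## metagene peaks
  peaks <- list()
  for (lb in libs) {
    for (anchor in c("start", "stop")) {
      prof <- metagene(tracks[[lb]], tx, anchor = anchor,
                       offsets = cfg$metagene$offsets,
                       min_gene_len = cfg$filters$min_gene_len,
                       min_reads_per_codon = cfg$filters$min_reads_per_codon)
      peaks[[paste(lb, anchor, sep = "_")]] <- peak_offset(prof)
      write.table(data.frame(offset = prof$offset, mean = prof$mean,
                             n_genes = prof$n_genes),
                  file.path(outdir,
                            paste0("metagene_", lb, "_", anchor, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_bedgraph(tracks[[lb]], file.path(outdir, lb))
  }
  summary$peak_offsets <- peaks

  ## polarity
  pol <- polarity_ratio(tracks[[libs[1]]], tx)
  summary$polarity <- list(mean = pol$mean, median = pol$median)

  ## operon position ratios (needs two ribo libraries)
  if (all(c("rele", "mnase") %in% libs) && nrow(tx$operons)) {
    tug <- define_single_TUs(tx, rna_track, ribo_tracks = tracks,
                             max_fold = cfg$filters$max_fold,
                             min_rpkm = cfg$filters$min_rpkm)
    if (nrow(tug)) {
      pr <- position_ratios(tracks$rele, tracks$mnase, tug)
      write.table(pr, file.path(outdir, "operon_ratios.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      meds <- tapply(pr$ratio, pr$bin, median)
      summary$operon <- list(bin_medians = as.list(meds))
      first <- pr$ratio[pr$bin == "1"]
      last <- pr$ratio[pr$bin == ">=5"]
      if (length(first) && length(last)) {
        rs <- rank_sum_test(first, last)
        summary$operon$rank_sum <- list(U = rs$U, p = rs$p_value)
      }
    }
  }

  ## reading frame
  if ("rele" %in% libs) {
    before <- subcodon_fractions(tracks$rele, tx,
                                 exclude_end_nt = cfg$filters$exclude_end_nt)
    shifted <- nnc_shift(tracks$rele, tx, tx)
    after <- subcodon_fractions(shifted, tx,
                                exclude_end_nt = cfg$filters$exclude_end_nt)
    summary$frame <- list(before = as.list(setNames(before$fraction,
                                                    paste0("f", 1:3))),
                          after = as.list(setNames(after$fraction,
                                                   paste0("f", 1:3))))
    hm <- codon_heatmap(tracks$rele, tx, tx)
    write.table(data.frame(codon = rownames(hm$fraction),
                           round(hm$fraction, 6)),
                file.path(outdir, "codon_heatmap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- list()
    for (gid in tx$genes$gene_id) {
      cl <- frameshift_scan(tracks$rele, gid, tx, genome = tx)
      if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
    }
    calls <- if (length(calls)) do.call(rbind, calls)
             else data.frame(gene_id = character(), codon = integer(),
                             frame_before = integer(),
                             frame_after = integer(),
                             direction = character(), score = numeric())
    write.table(calls, file.path(outdir, "frameshift_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$frameshift_calls <- calls
  }

  ## specificity
  bias <- list()
  for (lb in libs) {
    eb <- end_bias(fps[[lb]], tx)
    bias[[lb]] <- as.list(as.data.frame(eb$enrichment))
    write.table(data.frame(position = rownames(eb$freq),
                           round(eb$freq, 6)),
                file.path(outdir, paste0("end_bias_", lb, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  eb_rna <- end_bias(rna_fp, tx)
  bias$rnaseq <- as.list(as.data.frame(eb_rna$enrichment))
  summary$end_bias_enrichment <- bias
  lh <- length_histogram(do.call(rbind, fps))
  summary$median_length <- as.list(lh$median)
  if (all(c("rele", "mnase") %in% libs)) {
    pc <- per_gene_correlation(tracks$rele, tracks$mnase, tx)
    summary$per_gene_correlation <- pc
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  invisible(summary)
}
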