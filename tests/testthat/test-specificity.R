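# Nuclease sequence specificity, ORF composition, length histograms,
# per-gene robustness.

test_that("end bias recovers the MNase A/T preference parameter", {
  tx <- tiny_tx(seed = 91)
  sn <- place_ribosomes(tx, 800, seed = 1)
  for (p in c(0.6, 0.8, 1.0)) {
    fp <- digest(sn, tx, "mnase",
                 mnase = nuclease_model("MNASE", p_cut_before_AT = p),
                 seed = 2)
    eb <- end_bias(fp, tx)
    at1 <- sum(eb$freq["1", c("A", "T")])
    # binomial error plus the small probability that no (non-)A/T site
    # exists within the repositioning window
    tol <- 3 * sqrt(0.25 / eb$n_used) + 0.012
    expect_lt(abs(at1 - p), tol)
  }
})

test_that("end bias shows RelE -1 C / +1 G enrichment scaling with weights", {
  tx <- tiny_tx(seed = 92)
  sn <- place_ribosomes(tx, 1500, seed = 3)
  enr <- sapply(c(1, 3, 5), function(w) {
    fp <- digest(sn, tx, "rele",
                 rele = nuclease_model("RELE", w_minus1_C = w,
                                       w_plus1_G = w),
                 mnase = mnase_plain(), seed = 4)
    eb <- end_bias(fp, tx)
    c(C = eb$enrichment["-1", "C"], G = eb$enrichment["1", "G"])
  })
  expect_gt(enr["C", 2], 1.1)
  expect_gt(enr["G", 2], 1.1)
  expect_true(all(diff(enr["C", ]) > 0))
  expect_true(all(diff(enr["G", ]) > 0))
  # with the NNC rule and the weights both off, no residual end bias
  fp0 <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 0),
                mnase = mnase_plain(), seed = 4)
  eb0 <- end_bias(fp0, tx)
  expect_true(all(abs(eb0$enrichment[c("-1", "1"), ] - 1) < 0.12))
})

test_that("uniform RNA-seq fragments carry no end bias", {
  tx <- tiny_tx(seed = 93)
  rna <- simulate_rnaseq(tx, n_reads = 1e5, seed = 5)
  eb <- end_bias(rna, tx)
  expect_true(all(abs(eb$enrichment - 1) < 0.05))
  expect_equal(unname(rowSums(eb$freq)), rep(1, 4))
})

test_that("ORF position bias reflects codon usage", {
  tx <- tiny_tx(seed = 94)
  b <- orf_position_bias(tx$genome, tx)
  expect_equal(unname(rowSums(b)), rep(1, 3))
  # uniform usage: second positions near uniform
  expect_true(all(abs(b[2, ] - 0.25) < 0.05))
  # A/T-rich second codon positions by construction
  sc <- sense_codons()
  at2 <- substr(sc, 2, 2) %in% c("A", "T")
  usage <- setNames(ifelse(at2, 4, 1), sc)
  usage <- usage / sum(usage)
  tx2 <- generate_transcriptome(6, codon_usage = usage, seed = 95)
  b2 <- orf_position_bias(tx2$genome, tx2)
  atfrac <- rowSums(b2[, c("A", "T")])
  expect_identical(unname(which.max(atfrac)), 2L)
  # single tiny ORF against a hand count: ATG GAT TTC TAA
  genome1 <- Biostrings::DNAStringSet(c(c1 = "ATGGATTTCTAA"))
  ann1 <- data.frame(gene_id = "g1", contig = "c1", strand = "+",
                     start = 0L, end = 12L)
  b3 <- orf_position_bias(genome1, ann1)
  expect_equal(unname(b3[1, ]), c(1, 0, 1, 2) / 4)   # A,C,G,T at position 1
  expect_equal(unname(b3[2, ]), c(2, 0, 0, 2) / 4)
  expect_equal(unname(b3[3, ]), c(1, 1, 1, 1) / 4)
})

test_that("RelE footprints are 11 nt shorter than MNase footprints", {
  tx <- tiny_tx(seed = 96)
  sn <- place_ribosomes(tx, 400, seed = 6)
  fpr <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 0),
                mnase = mnase_plain(), seed = 7)
  fpm <- digest(sn, tx, "mnase", mnase = mnase_plain(), seed = 8)
  lh <- length_histogram(rbind(fpr, fpm))
  expect_equal(unname(lh$median["MNASE"] - lh$median["RELE"]), 11)
  expect_identical(nrow(length_histogram(fpr[0, ])$histogram), 0L)
})

test_that("per-gene counts are robust to the nuclease used", {
  tx <- tiny_tx(seed = 97)
  # genes at graded expression levels so there is true variance to recover
  sn <- do.call(rbind, lapply(seq_len(nrow(tx$genes)), function(i)
    place_ribosomes(tx, 80 * i, genes = tx$genes$gene_id[i],
                    seed = 9 + i)))
  trr <- assign_3prime_density(
    footprints_as_reads(digest(sn, tx, "rele", seed = 10)), tx)
  trm <- assign_3prime_density(
    footprints_as_reads(digest(sn, tx, "mnase", seed = 11)), tx)
  expect_equal(per_gene_correlation(trr, trr, tx)$pearson_log, 1)
  pc <- per_gene_correlation(trr, trm, tx)
  expect_gt(pc$pearson_log, 0.95)
  expect_error(per_gene_correlation(trr, zero_track(tx), tx),
               "fewer than 3")
})
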