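# Nuclease digestion geometry, sequence rules, and the RNA-seq fragment
# model.

test_that("geometry closure: exact boundary offsets with effects disabled", {
  tx <- tiny_tx(seed = 21)
  sn <- place_ribosomes(tx, 150, seed = 1)
  # MNase: every 3' end exactly delta_mnase past the A-site first nt
  fpm <- digest(sn, tx, "mnase", rele = rele_plain(),
                mnase = mnase_plain(), seed = 2)
  fpm <- fpm[!fpm$truncated, ]
  expect_true(all(fp_gene_offset(fpm, tx) -
                    fpm$a_off == nuclease_model("MNASE")$delta_mnase))
  # RelE: +1 for non-NNC, +2 for NNC (p_nnc = 1), both strands
  fpr <- digest(sn, tx, "rele", rele = rele_plain(),
                mnase = mnase_plain(), seed = 3)
  fpr <- fpr[!fpr$truncated, ]
  delta <- fp_gene_offset(fpr, tx) - fpr$a_off
  third <- vapply(seq_len(nrow(fpr)), function(i) {
    g <- tx$genes[match(fpr$gene_id[i], tx$genes$gene_id), ]
    substr(g$cds_seq, fpr$a_off[i] + 3, fpr$a_off[i] + 3)
  }, "")
  expect_true(all(delta[third != "C"] == 1))
  expect_true(all(delta[third == "C"] == 2))
  expect_true(all(c("+", "-") %in%
                    tx$genes$strand[match(fpr$gene_id,
                                          tx$genes$gene_id)]))
})

test_that("initiation-complex worked examples: +4 (RelE) and +15 (MNase)", {
  tx <- tiny_tx(seed = 22)
  g1 <- tx$genes$gene_id[1]
  sn <- data.frame(tu_id = tx$genes$tu_id[1], gene_id = g1, a_off = 3L,
                   occupied = FALSE, stalled = FALSE)
  fpr <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 0),
                mnase = mnase_plain(), seed = 1)
  expect_true(all(fp_gene_offset(fpr, tx) == 4L))
  fpm <- digest(sn, tx, "mnase", mnase = mnase_plain(), seed = 1)
  expect_true(all(fp_gene_offset(fpm, tx) == 15L))
})

test_that("NNC codons are cut after the 3rd nucleotide", {
  tx <- tiny_tx(seed = 23)
  g <- tx$genes[1, ]
  codons <- substring(g$cds_seq, seq(1, nchar(g$cds_seq), 3),
                      seq(3, nchar(g$cds_seq), 3))
  idx <- which(substr(codons, 3, 3) == "C" & seq_along(codons) > 1)[1]
  sn <- data.frame(tu_id = g$tu_id, gene_id = g$gene_id,
                   a_off = 3L * (idx - 1L), occupied = FALSE,
                   stalled = FALSE)
  fp <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 1),
               mnase = mnase_plain(), seed = 1)
  expect_identical(fp_gene_offset(fp, tx), fp$a_off + 2L)
})

test_that("occupied A sites are protected and digested by MNase instead", {
  tx <- tiny_tx(seed = 24)
  sn <- place_ribosomes(tx, 100, p_occupied = 1, seed = 1)
  fp <- digest(sn, tx, "rele", rele = rele_plain(p_block_occupied = 1),
               mnase = mnase_plain(), seed = 2)
  expect_true(all(fp$nuclease == "MNASE"))
  expect_true(all(fp_gene_offset(fp, tx)[!fp$truncated] -
                    fp$a_off[!fp$truncated] == 12L))
})

test_that("configurable geometry flows through to footprints", {
  tx <- tiny_tx(seed = 25)
  sn <- place_ribosomes(tx, 100, seed = 1)
  fp <- digest(sn, tx, "rele",
               rele = rele_plain(delta_rele = 2, p_nnc = 0),
               mnase = mnase_plain(delta_mnase = 9), seed = 2)
  expect_true(all(fp_gene_offset(fp, tx)[!fp$truncated] -
                    fp$a_off[!fp$truncated] == 2L))
})

test_that("digestion is reproducible given a seed", {
  tx <- tiny_tx(seed = 26)
  sn <- place_ribosomes(tx, 100, seed = 1)
  expect_identical(digest(sn, tx, "rele", seed = 9),
                   digest(sn, tx, "rele", seed = 9))
})

test_that("RNA-seq fragments are uniform and seed-stable", {
  tx <- generate_transcriptome(1, gene_length_range = c(900, 900),
                               seed = 31)
  fp <- simulate_rnaseq(tx, n_reads = 60000, seed = 5)
  expect_identical(fp, simulate_rnaseq(tx, n_reads = 60000, seed = 5))
  # flat coverage: coefficient of variation of interior per-nt coverage
  tu <- tx$tus[1, ]
  cov <- integer(tu$length)
  t5 <- if (tu$strand == "+") fp$start - tu$start
        else tu$end - fp$end
  for (i in seq_len(nrow(fp)))
    cov[(t5[i] + 1):(t5[i] + fp$length[i])] <-
      cov[(t5[i] + 1):(t5[i] + fp$length[i])] + 1L
  interior <- cov[61:(tu$length - 61)]
  expect_lt(sd(interior) / mean(interior), 0.1)
  expect_error(simulate_rnaseq(tx, abundance = c(g0001 = 0)), "zero")
})
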