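# Sub-codon frame quantification, A-site attribution, codon heatmap,
# NNC shift, frameshift scanning.

test_that("sub-codon fractions map offsets to positions 1/2/3", {
  tx <- generate_transcriptome(1, gene_length_range = c(300, 300),
                               seed = 71)
  g <- tx$genes[1, ]
  # all density at 2nd nucleotides of interior codons -> (0, 1, 0)
  tr <- add_ends(zero_track(tx), g, seq(31, 260, 3), 4)
  fs <- subcodon_fractions(tr, tx)
  expect_equal(fs$fraction, c(0, 1, 0))
  # reads inside the 30-nt ORF margins are excluded
  tr2 <- add_ends(tr, g, c(1, 4, 7, 271, 274), 50)
  fs2 <- subcodon_fractions(tr2, tx, exclude_end_nt = 30)
  expect_identical(fs2$counts, fs$counts)
  fs3 <- subcodon_fractions(tr2, tx, exclude_end_nt = 0)
  expect_gt(fs3$counts[2], fs$counts[2])
  # empty region is flagged, not an error
  fs4 <- subcodon_fractions(zero_track(tx), tx)
  expect_identical(fs4$n_reads, 0)
  expect_true(all(is.na(fs4$fraction)))
})

test_that("frame fractions match the codon-usage closed form", {
  # with unit context weights and p_nnc = 1, the fraction of ends at
  # sub-codon position 3 equals the NNC fraction among decoded codons
  tx <- generate_transcriptome(6, gene_length_range = c(600, 900),
                               seed = 72)
  sn <- place_ribosomes(tx, 800, frac_init = 0, frac_term = 0, seed = 1)
  fp <- digest(sn, tx, "rele", rele = rele_plain(), mnase = mnase_plain(),
               seed = 2)
  tr <- assign_3prime_density(footprints_as_reads(fp), tx)
  fs <- subcodon_fractions(tr, tx)
  # oracle: NNC fraction among the A-site codons actually sampled,
  # restricted to the interior window used by subcodon_fractions
  third_all <- vapply(seq_len(nrow(fp)), function(i) {
    g <- tx$genes[match(fp$gene_id[i], tx$genes$gene_id), ]
    substr(g$cds_seq, fp$a_off[i] + 3, fp$a_off[i] + 3)
  }, "")
  end_off <- fp$a_off + ifelse(third_all == "C", 2L, 1L)
  len <- (tx$genes$end - tx$genes$start)[match(fp$gene_id,
                                               tx$genes$gene_id)]
  keep <- end_off >= 30 & end_off < len - 30
  expect_equal(fs$fraction[3], mean(third_all[keep] == "C"),
               tolerance = 1e-9)
  expect_true(fs$fraction[2] > fs$fraction[3])
  expect_true(fs$fraction[3] > fs$fraction[1])
})

test_that("3'-UTR density carries no frame signal", {
  tx <- generate_transcriptome(6, gene_length_range = c(450, 600),
                               seed = 73)
  rna <- simulate_rnaseq(tx, n_reads = 150000, seed = 3)
  tr <- assign_3prime_density(footprints_as_reads(rna), tx)
  fs <- subcodon_fractions(tr, tx, region = "utr3")
  expect_gt(fs$n_reads, 1000)
  expect_equal(fs$fraction, rep(1 / 3, 3), tolerance = 0.05)
})

test_that("A-site attribution inverts digestion geometry", {
  tx <- tiny_tx(seed = 74)
  g <- tx$genes[1, ]
  # worked examples
  end4 <- if (g$strand == "+") g$start + 4 else g$end - 5
  a <- asite_codon_from_3prime(end4, g, "rele", tx$genome)
  expect_identical(a$codon, 2L)
  stop12 <- if (g$strand == "+") g$end - 3 + 12 else g$start + 2 - 12
  m <- asite_codon_from_3prime(stop12, g, "mnase")
  expect_identical(m$codon, g$n_codons)
  # position-3 end on a non-C codon is ambiguous
  codons <- substring(g$cds_seq, seq(1, nchar(g$cds_seq), 3),
                      seq(3, nchar(g$cds_seq), 3))
  k <- which(substr(codons, 3, 3) != "C")[3]
  end3 <- if (g$strand == "+") g$start + 3 * k - 1 else g$end - 3 * k
  amb <- asite_codon_from_3prime(end3, g, "rele", tx$genome)
  expect_true(amb$ambiguous)
  # full inversion on the simulator truth table
  sn <- place_ribosomes(tx, 200, seed = 4)
  fp <- digest(sn, tx, "rele", rele = rele_plain(), mnase = mnase_plain(),
               seed = 5)
  fp <- fp[!fp$truncated, ]
  hit <- vapply(seq_len(nrow(fp)), function(i) {
    gg <- tx$genes[match(fp$gene_id[i], tx$genes$gene_id), ]
    aa <- asite_codon_from_3prime(fp$three_pos[i], gg, "rele", tx$genome)
    isTRUE(aa$codon == fp$a_codon[i])
  }, TRUE)
  expect_true(all(hit))
})

test_that("codon heatmap shows the NNC pattern and its limits", {
  tx <- tiny_tx(seed = 75)
  sn <- place_ribosomes(tx, 1200, frac_init = 0, frac_term = 0, seed = 6)
  fp1 <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 1),
                mnase = mnase_plain(), seed = 7)
  hm <- codon_heatmap(assign_3prime_density(footprints_as_reads(fp1), tx),
                      tx, tx)
  nnc <- substr(rownames(hm$fraction), 3, 3) == "C"
  covered <- rowSums(hm$counts) >= 50
  expect_true(all(apply(hm$fraction[nnc & covered, ], 1,
                        which.max) == 3))
  expect_true(all(apply(hm$fraction[!nnc & covered, ], 1,
                        which.max) == 2))
  # p_nnc = 0 limit: everything cut after the second nucleotide
  fp0 <- digest(sn, tx, "rele", rele = rele_plain(p_nnc = 0),
                mnase = mnase_plain(), seed = 8)
  hm0 <- codon_heatmap(assign_3prime_density(footprints_as_reads(fp0), tx),
                       tx, tx)
  cov0 <- rowSums(hm0$counts) >= 50
  expect_true(all(apply(hm0$fraction[cov0, ], 1, which.max) == 2))
  # zero-read rows flagged
  expect_true(all(rownames(hm$counts)[rowSums(hm$counts) == 0] %in%
                    hm$flagged))
})

test_that("NNC shift moves exactly the 3rd-position density of NNC codons", {
  tx <- generate_transcriptome(1, gene_length_range = c(300, 300),
                               seed = 76)
  g <- tx$genes[1, ]
  codons <- substring(g$cds_seq, seq(1, 300, 3), seq(3, 300, 3))
  kc <- which(substr(codons, 3, 3) == "C")[2]
  kg <- which(substr(codons, 3, 3) == "G")[2]
  tr <- add_ends(zero_track(tx), g, c(3 * kc - 1, 3 * kg - 1), 5)
  sh <- nnc_shift(tr, tx, tx)
  vec <- releseq:::.gene_vec(sh, g)
  expect_identical(vec[3 * kc], 0L)          # NNC 3rd nt emptied
  expect_identical(vec[3 * kc - 1], 5L)      # moved to the 2nd nt
  expect_identical(vec[3 * kg], 5L)          # non-NNC untouched
  expect_identical(sum(vec), 10L)
})

test_that("NNC shift conserves totals and never lowers f2", {
  for (seed in c(81, 82, 83)) {
    tx <- tiny_tx(seed = seed, n_genes = 6)
    tr <- placement_track(tx, 400, seed = seed, digest_seed = seed + 1)
    sh <- nnc_shift(tr, tx, tx)
    tot <- function(t) sum(vapply(t$counts, function(x)
      sum(x[["+"]]) + sum(x[["-"]]), 0))
    expect_identical(tot(tr), tot(sh))
    f_before <- subcodon_fractions(tr, tx)$fraction[2]
    f_after <- subcodon_fractions(sh, tx)$fraction[2]
    expect_gte(f_after, f_before)
  }
})

test_that("f2 after the shift matches the mis-cleavage closed form", {
  tx <- generate_transcriptome(8, gene_length_range = c(600, 900),
                               seed = 84)
  sn <- place_ribosomes(tx, 1500, frac_init = 0, frac_term = 0, seed = 9)
  pm <- 0.1
  fp <- digest(sn, tx, "rele",
               rele = rele_plain(p_nnc = 1, p_miscleave = pm),
               mnase = mnase_plain(), seed = 10)
  tr <- assign_3prime_density(footprints_as_reads(fp), tx)
  sh <- nnc_shift(tr, tx, tx)
  f2 <- subcodon_fractions(sh, tx)$fraction[2]
  # closed form: non-mis-cleaved ends all reach position 2 after the
  # shift; mis-cleaved ends are uniform over the three positions, and
  # their position-3 share on NNC codons is shifted back as well
  nnc_frac <- mean(vapply(seq_len(nrow(tx$genes)), function(i) {
    cds <- tx$genes$cds_seq[i]
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    mean(substr(codons, 3, 3) == "C")
  }, 0))
  expected <- (1 - pm) + pm / 3 + pm / 3 * nnc_frac
  se <- sqrt(expected * (1 - expected) / sum(fp$length > 0))
  expect_lt(abs(f2 - expected), 3 * se + 0.005)
})

test_that("frameshift scan recovers the prfB-like +1 event", {
  tx <- fs_tx(seed = 85)
  sn <- place_ribosomes(tx, 1200, seed = 11)
  tr <- placement_track(tx, 1200, seed = 11, digest_seed = 12)
  call <- frameshift_scan(tr, tx$genes$gene_id[1], tx, genome = tx)
  expect_false(is.null(call))
  expect_lte(abs(call$codon - 28), 1)
  expect_identical(call$direction, "+1")
  expect_gt(call$score, 50)
})

test_that("frameshift scan detects a -1 shift and stays silent otherwise", {
  tx <- generate_transcriptome(1, gene_length_range = c(300, 300),
                               seed = 86)
  g <- tx$genes[1, ]
  # -1-frame A sites downstream of codon 40, built from the truth model
  up <- 3 * (1:39)
  down <- 3 * 39 - 1 + 3 * (0:40)
  sn <- data.frame(tu_id = g$tu_id, gene_id = g$gene_id,
                   a_off = c(rep(up, each = 8), rep(down, each = 8)),
                   occupied = FALSE, stalled = FALSE)
  fp <- digest(sn, tx, "rele", seed = 13)
  tr <- assign_3prime_density(footprints_as_reads(fp), tx)
  call <- frameshift_scan(tr, g, genome = tx)
  expect_false(is.null(call))
  expect_lte(abs(call$codon - 40), 1)
  expect_identical(call$direction, "-1")
  # no-shift gene: no call
  sn0 <- place_ribosomes(tx, 900, seed = 14)
  tr0 <- assign_3prime_density(
    footprints_as_reads(digest(sn0, tx, "rele", seed = 15)), tx)
  expect_null(frameshift_scan(tr0, g, genome = tx))
  # insufficient reads: no scan, message
  expect_message(
    expect_null(frameshift_scan(zero_track(tx), g, genome = tx)),
    "no scan")
})
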