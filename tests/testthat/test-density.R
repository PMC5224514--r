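# 3'-end assignment, gene statistics and filters, metagene profiles,
# peak calling, polarity.

test_that("3'-end assignment follows the strand conventions", {
  genome <- Biostrings::DNAStringSet(c(ctg = strrep("A", 200)))
  reads <- data.frame(contig = "ctg",
                      strand = c("+", "-", "+", "+"),
                      start = c(100L, 100L, 100L, 100L),
                      end = c(130L, 130L, 130L, 130L))
  tr <- assign_3prime_density(reads, genome)
  expect_identical(tr$counts$ctg[["+"]][130], 3L)   # end-1 = 129 (0-based)
  expect_identical(tr$counts$ctg[["-"]][101], 1L)   # start = 100
  expect_identical(sum(tr$counts$ctg[["+"]]) + sum(tr$counts$ctg[["-"]]),
                   nrow(reads))
})

test_that("density totals are conserved for random read sets", {
  genome <- Biostrings::DNAStringSet(c(a = strrep("C", 500),
                                       b = strrep("G", 300)))
  set.seed(77)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    ctg <- sample(c("a", "b"), n, replace = TRUE)
    st <- ifelse(ctg == "a", 500L, 300L) - 40L
    s <- floor(runif(n) * st)
    reads <- data.frame(contig = ctg,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        start = s, end = s + 30L)
    tr <- assign_3prime_density(reads, genome)
    expect_identical(sum(vapply(tr$counts, function(x)
      sum(x[["+"]]) + sum(x[["-"]]), 0)), as.double(n))
  }
})

test_that("reads-per-codon filter uses a strict threshold", {
  tx <- generate_transcriptome(3, gene_length_range = c(900, 900),
                               seed = 51)
  tr <- zero_track(tx)
  g <- tx$genes
  tr <- add_ends(tr, g[1, ], seq_len(29) * 3, 1)      # 29 reads, 300 codons
  tr <- add_ends(tr, g[2, ], seq_len(30) * 3, 1)      # 30 reads -> exactly 0.1
  gs <- gene_stats(tr, tx, min_reads_per_codon = 0.1)
  expect_equal(gs$stats$reads_per_codon[1], 29 / 300)
  expect_false(g$gene_id[1] %in% gs$retained)         # 0.0967 < 0.1
  expect_true(g$gene_id[2] %in% gs$retained)          # threshold is "less than"
  expect_false(g$gene_id[3] %in% gs$retained)         # zero reads
  expect_equal(gs$stats$rpkm[2], 30 / 0.9 / (59 / 1e6))
})

test_that("metagene equals the per-gene pattern and is equal-weighted", {
  tx <- generate_transcriptome(4, gene_length_range = c(1200, 1500),
                               seed = 52)
  tr <- zero_track(tx)
  for (i in 1:4) tr <- add_ends(tr, tx$genes[i, ], 15, 10 * i)
  prof <- metagene(tr, tx, "start", offsets = c(-20, 30),
                   min_gene_len = 1000, min_reads_per_codon = NULL)
  expect_identical(peak_offset(prof), 15L)
  expect_identical(prof$n_genes, 4L)
  # delta profile: all mass at +15 after mean-normalization
  expect_true(all(prof$mean[prof$offset != 15] == 0))
  # invariant under gene reordering and duplication of a gene's density
  genes2 <- tx$genes[c(3, 1, 4, 2, 1), ]
  prof2 <- metagene(tr, genes2, "start", offsets = c(-20, 30),
                    min_gene_len = 1000, min_reads_per_codon = NULL)
  expect_equal(prof2$mean, prof$mean)
})

test_that("peak_offset breaks ties 5'-ward and validates windows", {
  prof <- structure(list(offset = -5:5, mean = rep(1, 11), n_genes = 1,
                         anchor = "START", normalization = "raw"),
                    class = "MetageneProfile")
  expect_warning(p <- peak_offset(prof), "tied")
  expect_identical(p, -5L)
  expect_error(peak_offset(prof, c(10, 20)), "empty")
  prof$mean[8] <- 2
  expect_identical(peak_offset(prof, c(0, 5)), 2L)
})

test_that("metagene peaks track configured nuclease deltas", {
  tx <- generate_transcriptome(10, gene_length_range = c(600, 900),
                               seed = 53)
  sn <- place_ribosomes(tx, 300, seed = 1)
  for (d in list(c(rele = 2, mnase = 9), c(rele = 1, mnase = 12))) {
    fpr <- digest(sn, tx, "rele",
                  rele = rele_plain(delta_rele = d["rele"], p_nnc = 0),
                  mnase = mnase_plain(delta_mnase = d["mnase"]), seed = 2)
    fpm <- digest(sn, tx, "mnase",
                  mnase = mnase_plain(delta_mnase = d["mnase"]), seed = 3)
    trr <- assign_3prime_density(footprints_as_reads(fpr), tx)
    trm <- assign_3prime_density(footprints_as_reads(fpm), tx)
    expect_identical(peak_offset(metagene(trr, tx, "start",
                                          offsets = c(-20, 30),
                                          min_gene_len = 400)),
                     as.integer(d["rele"] + 3))
    expect_identical(peak_offset(metagene(trm, tx, "start",
                                          offsets = c(-20, 30),
                                          min_gene_len = 400)),
                     as.integer(d["mnase"] + 3))
  }
})

test_that("polarity ratio behaves at the uniform and degenerate limits", {
  tx <- generate_transcriptome(1, gene_length_range = c(900, 900),
                               seed = 54)
  g <- tx$genes[1, ]
  tr <- add_ends(zero_track(tx), g, seq(1, 898, 3), 2)  # uniform 2/codon
  pol <- polarity_ratio(tr, tx)
  expect_equal(pol$per_gene$ratio, 1, tolerance = 0.01)
  # all density in the head: finite, large
  tr2 <- add_ends(zero_track(tx), g, seq(1, 298, 3), 5)
  pol2 <- polarity_ratio(tr2, tx)
  expect_gt(pol2$per_gene$ratio, 100)
  expect_true(is.finite(pol2$per_gene$ratio))
})
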