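test_that("expression generator is seeded, honest about truth, and sized right", {
  a <- gen_expression(n_genes = 300, n_planted = 30, seed = 4)
  b <- gen_expression(n_genes = 300, n_planted = 30, seed = 4)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$planted, b$truth$planted)
  c2 <- gen_expression(n_genes = 300, n_planted = 30, seed = 5)
  expect_false(identical(a$matrix$values, c2$matrix$values))

  z <- gen_expression(n_genes = 100, n_planted = 0, seed = 1)
  expect_equal(nrow(z$truth$planted), 0)

  expect_equal(dim(a$matrix$values), c(300, 10))
  expect_equal(table(a$matrix$classes)[["control"]], 4)

  # planted shift recovers the recorded fold within normal-theory bounds
  ex <- gen_expression(n_genes = 2000, n_planted = 200, sigma = 0.5,
                       fold_range = c(8, 8), seed = 9)
  idx <- match(ex$truth$planted$gene_id, rownames(ex$matrix$values))
  cls <- ex$matrix$classes
  diff_obs <- rowMeans(ex$matrix$values[idx, cls == "E2"]) -
    rowMeans(ex$matrix$values[idx, cls == "control"])
  sgn <- ifelse(ex$truth$planted$direction == "up", 1, -1)
  expect_true(all(abs(diff_obs - sgn * 3) < 3 * 0.5 / sqrt(3) * 2.5))

  expect_error(gen_expression(n_genes = 10, n_planted = 10),
               class = "estrocon_design_error")
  expect_error(gen_expression(n_per_class = c(4, 1, 3)),
               class = "estrocon_design_error")
})

test_that("spot tables round-trip through normalization to the true ratios", {
  ex <- gen_expression(n_genes = 400, n_planted = 40, seed = 6)
  dir <- tempfile()
  paths <- gen_spot_tables(ex$matrix, dir, bias_coef = 0.3,
                           missing_rate = 0.02, seed = 7)
  expect_length(paths, 10)
  spots <- lapply(paths, read_spot_table)
  ratios <- lapply(spots, lowess_normalize)
  em <- build_matrix(ratios, ex$matrix$classes,
                     spot_ids = spots[[1]]$spot_id)
  common <- intersect(rownames(em$values), rownames(ex$matrix$values))
  err <- em$values[common, ] - ex$matrix$values[common, ]
  # bias is removed; residual error is the smoother's, well under sigma
  expect_lt(median(abs(err), na.rm = TRUE), 0.1)
})

test_that("genome generator plants recoverable motifs at honest rates", {
  gen <- gen_genome_and_loci(n_chrom = 1, chrom_len = 1e6, n_genes = 20,
                             gene_length = 2000, gc = 0.5,
                             background_motif_rate = 8, seed = 12)
  # base composition near uniform: 99% binomial interval around 0.25
  tab <- Biostrings::alphabetFrequency(gen$genome[[1]])[c("A", "C", "G", "T")]
  p_hat <- tab / 1e6
  half <- 2.58 * sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(p_hat - 0.25) < half + 1e-3))

  # every recorded plant is recovered by the scanner
  hits <- scan_motif(gen$genome)
  planted <- gen$truth$planted_motif_positions
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$pos %in% hits$pos[hits$chrom == "chr1"]))

  # determinism and seed sensitivity
  gen2 <- gen_genome_and_loci(n_chrom = 1, chrom_len = 1e6, n_genes = 20,
                              gene_length = 2000, gc = 0.5,
                              background_motif_rate = 8, seed = 12)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))

  # no plants requested: flank hit rate stays at background
  gen0 <- gen_genome_and_loci(n_chrom = 1, chrom_len = 2e5, n_genes = 5,
                              gene_length = 1000, seed = 3)
  expect_equal(nrow(gen0$truth$planted_motif_positions), 0)

  expect_error(gen_genome_and_loci(n_chrom = 1, chrom_len = 1e4,
                                   n_genes = 50, gene_length = 500),
               class = "estrocon_packing_error")
})

test_that("homology, sites and cell-line lists hit their target rates", {
  gen <- gen_genome_and_loci(n_chrom = 2, chrom_len = 5e5, n_genes = 200,
                             gene_length = 800, seed = 31)
  fish <- sprintf("f%04d", 1:1000)
  resp <- fish[1:100]

  # homolog_rate = 1 maps everything
  r1 <- gen_regulome_and_sets(gen$loci, gen$chrom_lengths, fish, resp,
                              homolog_rate = 1, many_to_one = 0,
                              seed = 32)
  expect_equal(map_to_human(fish, r1$homology)$mapping_rate, 1)

  # overlap_fraction realized within a binomial 95% interval across seeds
  realized <- sapply(1:6, function(s) {
    rr <- gen_regulome_and_sets(gen$loci, gen$chrom_lengths, fish, resp,
                                overlap_fraction = 0.29, seed = s)
    resp_h <- rr$truth$mapped_responsive_human
    pooled <- unique(unlist(rr$cell_lines))
    length(intersect(resp_h, pooled)) / length(resp_h)
  })
  n_h <- 40  # approx mapped responsive genes per draw at rate 0.435
  expect_lt(abs(mean(realized) - 0.29),
            2 * sqrt(0.29 * 0.71 / (n_h * 6)) + 0.02)

  expect_error(
    gen_regulome_and_sets(gen$loci, gen$chrom_lengths, fish, resp,
                          overlap_fraction = 1.5),
    class = "estrocon_design_error")
  expect_error(
    gen_regulome_and_sets(gen$loci, gen$chrom_lengths, fish, resp,
                          enrich_factor = 0.5),
    class = "estrocon_design_error")

  # every conserved gene sits in at least one cell-line list
  rr <- gen_regulome_and_sets(gen$loci, gen$chrom_lengths, fish, resp,
                              seed = 33)
  pooled <- unique(unlist(rr$cell_lines))
  expect_true(all(rr$truth$conserved_human %in% pooled))
})

test_that("external formats written by the generator read back faithfully", {
  gen <- gen_genome_and_loci(n_chrom = 1, chrom_len = 1e5, n_genes = 10,
                             gene_length = 1000, seed = 41)
  reg <- gen_regulome_and_sets(gen$loci, gen$chrom_lengths,
                               sprintf("f%d", 1:50), sprintf("f%d", 1:10),
                               n_sites = 30, seed = 42)
  dir <- tempfile()
  paths <- write_synth_inputs(c(gen, reg), dir)
  expect_true(all(file.exists(paths)))

  genome2 <- Biostrings::readDNAStringSet(paths["genome"])
  expect_equal(as.character(genome2[[1]]), as.character(gen$genome[[1]]))
  loci2 <- read_bed(paths["loci"])
  expect_equal(loci2$start, gen$loci$start)
  expect_equal(loci2$gene_id, gen$loci$gene_id)
  hm <- read_homology_map(paths["homology"])
  expect_equal(hm$source_id, reg$homology$source_id)
  cl <- readLines(paths["cellline_1"])
  expect_equal(cl, reg$cell_lines$cellline_1)
})
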