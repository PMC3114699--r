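ere <- "GGTCAnnnTGACC"

test_that("motif scanning finds the consensus and matches a regex oracle", {
  g <- Biostrings::DNAStringSet(c(chrA = "GGTCAAAATGACC"))
  hits <- scan_motif(g, ere)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pos, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched, "GGTCAAAATGACC")

  expect_equal(nrow(scan_motif(Biostrings::DNAStringSet(
    c(chrA = strrep("T", 200))), ere)), 0)

  expect_error(scan_motif(g, "GGTCAXX"),
               class = "estrocon_pattern_error")
  expect_error(scan_motif(g, "GGT"), class = "estrocon_pattern_error")

  # seeded random sequences, exact equality with the brute-force oracle
  for (seed in 1:5) {
    sq <- random_dna(10000, seed)
    # spike in a few instances so counts are nonzero
    substr(sq, 1000, 1012) <- "GGTCAGTATGACC"
    substr(sq, 5000, 5012) <- "GGTCACCCTGACC"
    hits <- scan_motif(Biostrings::DNAStringSet(c(chr1 = sq)), ere)
    orc <- regex_scan_oracle(sq, ere)
    expect_identical(hits$pos, orc$pos)
    expect_identical(hits$strand, orc$strand)
  }

  # non-palindromic pattern reports both strands like the oracle
  sq <- random_dna(20000, 99)
  hits <- scan_motif(Biostrings::DNAStringSet(c(chr1 = sq)), "GGTCAn")
  orc <- regex_scan_oracle(sq, "GGTCAn")
  expect_identical(hits$pos, orc$pos)
  expect_identical(hits$strand, orc$strand)
})

test_that("reverse-complementing a sequence mirrors palindromic hit positions", {
  sq <- random_dna(5000, 7)
  substr(sq, 100, 112) <- "GGTCATTTTGACC"
  substr(sq, 900, 912) <- "GGTCAGGGTGACC"
  L <- nchar(sq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sq)))
  h1 <- scan_motif(Biostrings::DNAStringSet(c(c1 = sq)), ere)
  h2 <- scan_motif(Biostrings::DNAStringSet(c(c1 = rc)), ere)
  expect_identical(sort(h2$pos), sort(L - 13L - h1$pos))
})

test_that("flank extraction does interval arithmetic with clipping", {
  loci <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     start = c(50000L, 5000L), end = c(60000L, 9000L),
                     strand = "+")
  fl <- extract_flanks(loci, flank = 20000,
                       chrom_lengths = c(chr1 = 1e6))
  expect_equal(fl$start, c(30000L, 0L))
  expect_equal(fl$end, c(80000L, 29000L))
  # unclipped width = body + 2 * flank
  expect_equal(fl$end[1] - fl$start[1], 10000 + 2 * 20000)
  expect_error(extract_flanks(loci[, ], flank = 10,
                              chrom_lengths = c(chr9 = 10)),
               class = "estrocon_design_error")
})

test_that("motif enrichment reduces to the binomial tail on plants", {
  # whole-genome region: ratio 1, p = 1
  hits <- data.frame(chrom = "chr1", pos = c(10L, 500L, 900L),
                     strand = "+", matched = "x")
  whole <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  r <- motif_enrichment(hits, whole, genome_size = 1000)
  expect_equal(r$observed, 3)
  expect_equal(r$expected, 3)
  expect_equal(r$ratio, 1)

  expect_error(motif_enrichment(hits[0, ], whole, 1000),
               class = "estrocon_undefined_test")

  # planted 10x density in 1% of a synthetic genome: strong enrichment
  gen <- gen_genome_and_loci(n_chrom = 1, chrom_len = 4e5, n_genes = 4,
                             gene_length = 2000, flank = 500,
                             motif_genes = sprintf("h%05d", 1:4),
                             planted_motif_rate_in_flanks = 10,
                             background_motif_rate = 10, seed = 13)
  hits <- scan_motif(gen$genome)
  fl <- extract_flanks(gen$loci, flank = 500,
                       chrom_lengths = gen$chrom_lengths)
  res <- motif_enrichment(hits, fl, sum(gen$chrom_lengths))
  expect_lt(res$p_binomial, 0.01)
  expect_gt(res$ratio, 2)
})

test_that("site assignment respects the window and shifts equivariantly", {
  loci <- data.frame(gene_id = "g1", chrom = "chr1",
                     start = 200000L, end = 210000L, strand = "+")
  near <- data.frame(chrom = "chr1", start = 150000L, end = 150100L)
  far <- data.frame(chrom = "chr1", start = 320000L, end = 320100L)
  body <- data.frame(chrom = "chr1", start = 205000L, end = 205100L)
  expect_equal(unname(assign_sites(loci, near)$counts), 1L)
  expect_equal(unname(assign_sites(loci, far)$counts), 0L)
  expect_equal(unname(assign_sites(loci, body)$counts), 1L)

  # translation equivariance
  set.seed(4)
  loci2 <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                      start = as.integer(seq(1e5, 9e5, length.out = 10)),
                      end = as.integer(seq(1e5, 9e5, length.out = 10)) +
                        5000L, strand = "+")
  sites2 <- data.frame(chrom = "chr1",
                       start = as.integer(runif(50, 0, 9.5e5)))
  sites2$end <- sites2$start + 200L
  c1 <- assign_sites(loci2, sites2, window = 20000)$counts
  shift <- 12345L
  loci3 <- transform(loci2, start = start + shift, end = end + shift)
  sites3 <- transform(sites2, start = start + shift, end = end + shift)
  expect_identical(assign_sites(loci3, sites3, window = 20000)$counts, c1)
})

test_that("site enrichment reports truncated per-gene rates and finds plants", {
  # 8 well-separated genes; 5 sites on distinct genes -> 5/8 = 0.625 -> 0.62
  loci <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                     start = as.integer((1:8) * 50000L),
                     end = as.integer((1:8) * 50000L + 1000L),
                     strand = "+")
  sites <- data.frame(chrom = "chr1",
                      start = as.integer((1:5) * 50000L + 2000L))
  sites$end <- sites$start + 100L
  res <- site_enrichment(loci$gene_id, loci, sites, window = 5000,
                         n_rand = 50, seed = 1)
  expect_equal(res$observed, 5)
  expect_equal(res$per_gene_rate, 0.62)
  expect_equal(res$genes_with_site, 5)

  expect_error(site_enrichment("nope", loci, sites),
               class = "estrocon_membership_error")

  # planted 3x density in target windows is detected
  gen <- gen_genome_and_loci(n_chrom = 2, chrom_len = 5e5, n_genes = 80,
                             gene_length = 1000, seed = 21)
  reg <- gen_regulome_and_sets(
    gen$loci, gen$chrom_lengths,
    source_ids = sprintf("f%d", 1:200),
    responsive_ids = sprintf("f%d", 1:40),
    target_genes = gen$loci$gene_id[seq(1, 80, by = 5)],
    n_sites = 400, enrich_factor = 3, window = 4000, seed = 22)
  res <- site_enrichment(reg$truth$conserved_human, gen$loci, reg$sites,
                         window = 4000, n_rand = 500, seed = 23)
  expect_lte(res$p_empirical, 0.01)
  expect_gt(res$observed, res$expected)
})

test_that("BED round-trip preserves 0-based half-open intervals", {
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 100L),
                   end = c(50L, 200L), gene_id = c("a", "b"),
                   strand = c("+", "-"))
  p <- tempfile(fileext = ".bed")
  write_bed(df, p)
  back <- read_bed(p)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$gene_id, df$gene_id)
  expect_equal(back$strand, df$strand)
})
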