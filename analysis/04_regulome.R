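#!/usr/bin/env Rscript
# Stage 4: regulatory-region analysis of the conserved genes.
#
# Scans the genome for the estrogen response element (ERE, the palindromic
# consensus GGTCAnnnTGACC), tests whether EREs concentrate in the flanking
# regions of conserved estrogen-responsive genes versus the genome-wide
# distribution, assigns ER binding sites to genes within a neighbourhood
# window, and tests binding-site enrichment in the conserved set against a
# randomization null (and a binomial null) over the full locus collection.

library(estrocon)

synth <- "results/synth"
out <- "results"
cfg <- read_config(file.path(synth, "config.yaml"))
sy <- cfg$synth
seed <- cfg$seed

genome <- Biostrings::readDNAStringSet(file.path(synth, "genome.fa"))
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
loci <- read_bed(file.path(synth, "loci.bed"))
sites <- read_bed(file.path(synth, "sites.bed"))
conserved <- readLines(file.path(out, "conserved_genes.txt"))
nonconserved <- readLines(file.path(out, "nonconserved_genes.txt"))

hits <- scan_motif(genome, "GGTCAnnnTGACC")
cat(sprintf("ERE scan: %d hits in %.1f Mb\n", nrow(hits),
            sum(chrom_lengths) / 1e6))

flanks <- extract_flanks(loci[loci$gene_id %in% conserved, ],
                         flank = sy$flank, chrom_lengths = chrom_lengths)
mres <- motif_enrichment(hits, flanks, sum(chrom_lengths))
cat(sprintf(
  "ERE in conserved flanks: observed %d, expected %.1f (ratio %.2f), p = %.3g\n",
  mres$observed, mres$expected, mres$ratio, mres$p_binomial))

sres <- site_enrichment(intersect(conserved, loci$gene_id), loci, sites,
                        window = sy$window, n_rand = cfg$thresholds$n_rand,
                        seed = seed + 6L)
cat(sprintf(
  "ER sites near conserved genes: %d observed vs %.1f expected (null mean),\n",
  sres$observed, sres$expected),
  sprintf("  %d of %d genes with >= 1 site, %.2f sites/gene, p_empirical = %.3g, p_binomial = %.3g\n",
          sres$genes_with_site, sres$n_targets, sres$per_gene_rate,
          sres$p_empirical, sres$p_binomial))

nc <- intersect(nonconserved, loci$gene_id)
nca <- assign_sites(loci[loci$gene_id %in% nc, ], sites,
                    window = sy$window)
cat(sprintf("non-conserved genes: %d sites over %d genes = %.2f sites/gene\n",
            nca$total, length(nc), trunc(100 * nca$total / length(nc)) / 100))

enr <- list(
  motif = mres,
  sites = sres,
  sites_per_gene_nonconserved = trunc(100 * nca$total / length(nc)) / 100)
jsonlite::write_json(enr, file.path(out, "regulome.json"),
                     auto_unbox = TRUE, digits = NA)
write_bed(data.frame(chrom = hits$chrom, start = hits$pos,
                     end = hits$pos + 13L, gene_id = hits$matched,
                     strand = hits$strand),
          file.path(out, "ere_hits.bed"))
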