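#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emits everything the later stages read, in the external formats the
# pipeline supports: per-array GenePix-style spot tables, a genome FASTA,
# gene loci and ER-binding sites as BED, a two-column homology map,
# one-id-per-line cell-line gene lists, and a truth record for scoring.

library(estrocon)

seed <- 20260927L
out <- "results/synth"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_config(seed = seed)
sy <- cfg$synth

ex <- gen_expression(n_genes = sy$n_genes, n_per_class = sy$n_per_class,
                     n_planted = sy$n_planted, sigma = sy$sigma,
                     rescue_fraction = sy$rescue_fraction,
                     fold_range = sy$fold_range, seed = seed)
paths <- gen_spot_tables(ex$matrix, file.path(out, "spots"),
                         bias_coef = sy$bias_coef,
                         missing_rate = sy$missing_rate, seed = seed + 1L)
write.table(data.frame(sample_id = names(paths),
                       class = ex$matrix$classes,
                       path = unname(paths)),
            file.path(out, "samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

gen <- gen_genome_and_loci(n_chrom = sy$n_chrom, chrom_len = sy$chrom_len,
                           n_genes = sy$n_human_genes, gc = sy$gc,
                           gene_length = sy$gene_length, flank = sy$flank,
                           background_motif_rate = sy$background_motif_rate,
                           seed = seed + 4L)
reg <- gen_regulome_and_sets(
  gen$loci, gen$chrom_lengths,
  source_ids = rownames(ex$matrix$values),
  responsive_ids = ex$truth$planted$gene_id,
  conserved_candidates = ex$truth$planted$gene_id[
    ex$truth$planted$fold >= sy$robust_min_fold],
  n_sites = sy$n_sites, enrich_factor = sy$enrich_factor,
  window = sy$window, site_width = sy$site_width,
  homolog_rate = sy$homolog_rate, many_to_one = sy$many_to_one,
  n_cell_lines = sy$n_cell_lines, cell_line_frac = sy$cell_line_frac,
  overlap_fraction = sy$overlap_fraction, seed = seed + 5L)

invisible(write_synth_inputs(c(gen, reg), out))
write.table(ex$truth$planted, file.path(out, "planted_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_config(cfg, file.path(out, "config.yaml"))

cat(sprintf(
  "simulated %d probes (%d planted responsive, %d robust >= %g-fold),\n",
  sy$n_genes, nrow(ex$truth$planted),
  sum(ex$truth$planted$fold >= sy$robust_min_fold), sy$robust_min_fold),
  sprintf("%d human loci on %d x %.0f kb chromosomes, %d binding sites,\n",
          sy$n_human_genes, sy$n_chrom, sy$chrom_len / 1e3, sy$n_sites),
  sprintf("%d planted conserved genes -> %s\n",
          length(reg$truth$conserved_fish), out))
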