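#!/usr/bin/env Rscript
# Stage 3: homolog mapping and cross-species conservation.
#
# Maps the responsive genes to the other species through the homology
# table, intersects the mapped set with each cell-line estrogen-responsive
# list and their pooled union, reports overlap percentages with binomial
# and hypergeometric significance against the full homolog universe, and
# writes the conserved / non-conserved split used by stage 4.

library(estrocon)

synth <- "results/synth"
out <- "results"
resp <- read.delim(file.path(out, "responsive_genes.tsv"))
hm <- read_homology_map(file.path(synth, "homology.tsv"))
cl_files <- list.files(synth, pattern = "^cellline_.*\\.txt$",
                       full.names = TRUE)
cell_lines <- lapply(cl_files, readLines)
names(cell_lines) <- sub("\\.txt$", "", basename(cl_files))

mp <- map_to_human(resp$gene_id, hm)
cat(sprintf("homolog mapping: %d / %d responsive genes (%.1f%%), %d unique\n",
            mp$n_mapped, mp$n_input, 100 * mp$mapping_rate,
            length(mp$human_ids)))

universe <- sort(unique(hm$target_id))
rows <- lapply(names(cell_lines), function(nm) {
  ov <- overlap_test(mp$human_ids, intersect(cell_lines[[nm]], universe),
                     universe)
  data.frame(set = nm, k = ov$overlap_k,
             percent = round(100 * ov$percent_overlap, 1),
             p_binomial = ov$p_binomial,
             p_hypergeometric = ov$p_hypergeometric)
})
pooled_ids <- sort(unique(intersect(unlist(cell_lines), universe)))
ovp <- overlap_test(mp$human_ids, pooled_ids, universe)
rows[[length(rows) + 1]] <- data.frame(
  set = "pooled", k = ovp$overlap_k,
  percent = round(100 * ovp$percent_overlap, 1),
  p_binomial = ovp$p_binomial, p_hypergeometric = ovp$p_hypergeometric)
overlaps <- do.call(rbind, rows)
print(overlaps, row.names = FALSE)
write.table(overlaps, file.path(out, "overlaps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

vc <- venn_counts(c(list(mapped_responsive = mp$human_ids),
                    lapply(cell_lines[1:3], intersect, universe)))
write.table(vc, file.path(out, "venn_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

conserved <- intersect(mp$human_ids, pooled_ids)
nonconserved <- setdiff(mp$human_ids, pooled_ids)
writeLines(conserved, file.path(out, "conserved_genes.txt"))
writeLines(nonconserved, file.path(out, "nonconserved_genes.txt"))
cat(sprintf("conserved: %d of %d mapped (%d%%); non-conserved: %d\n",
            length(conserved), length(mp$human_ids),
            round(100 * length(conserved) / length(mp$human_ids)),
            length(nonconserved)))
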