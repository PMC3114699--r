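#' Default pipeline configuration
#'
#' Every study threshold is a named key with the published value as
#' default: multiclass and two-class SAM q-value cutoffs (0.08), minimum
#' fold change (2), rescue fraction tau (0.25), missingness cap (6 of 10),
#' flank width (20 kb), binding-site neighbourhood (100 kb), permutation
#' and randomization counts (100 / 1000).  The `synth` block holds the
#' synthetic-data scale: 2000 genes on a 4+3+3 design, a 2 x 1 Mb
#' synthetic human genome, 500 binding sites; its `flank` and `window`
#' (5 kb) are the study geometry scaled to the ~1/1500-size genome.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param outdir output directory, or `NULL` for in-memory only.
#' @return nested named list (`RunConfig`).
#' @export
default_config <- function(seed = 1, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    thresholds = list(
      q_sam_3class = 0.08, q_sam_2class = 0.08,
      min_fold = 2, tau = 0.25, max_missing = 6, span = 0.3,
      flank = 20000, window = 100000,
      n_perm = 100, n_rand = 1000
    ),
    synth = list(
      n_genes = 2000, n_per_class = c(4, 3, 3), n_planted = 100,
      sigma = 0.5, rescue_fraction = 0.5, fold_range = c(2, 128),
      bias_coef = 0.2, missing_rate = 0.01,
      n_chrom = 2, chrom_len = 1e6, n_human_genes = 600,
      gene_length = 1000, gc = 0.41,
      flank = 5000, window = 5000,
      n_sites = 500, enrich_factor = 3, site_width = 200,
      homolog_rate = 0.435, many_to_one = 0.1,
      n_cell_lines = 4, cell_line_frac = 0.18,
      overlap_fraction = 0.29, robust_min_fold = 4,
      background_motif_rate = 10
    )
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return the configuration list (`read`); `path` invisibly (`write`).
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes every stage in order — array normalization, multiclass SAM
#' pre-filter, two-class SAM (E2 vs control), responsive-gene
#' classification with the anti-estrogen rescue criterion, homolog
#' mapping, cell-line overlap with significance, ERE motif scan and
#' flank-enrichment test, binding-site assignment and randomization-null
#' enrichment, and a Fisher gene-set enrichment — and returns a structured
#' report of all counts, rates and p-values.  With the same configuration
#' and seed the report is byte-identical across runs.
#'
#' @param config a configuration list, see [default_config()].
#' @return the report: a nested list; written as `report.json` (plus
#'   per-stage TSVs) under `config$outdir` when that is set.
#' @export
run_pipeline <- function(config = default_config()) {
  th <- config$thresholds
  sy <- config$synth
  seed <- config$seed
  out <- config$outdir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out))
      utils::write.table(df, file.path(out, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## stage: synthetic inputs -------------------------------------------
  ex <- gen_expression(
    n_genes = sy$n_genes, n_per_class = sy$n_per_class,
    n_planted = sy$n_planted, sigma = sy$sigma,
    rescue_fraction = sy$rescue_fraction, fold_range = sy$fold_range,
    seed = seed)
  spot_dir <- file.path(out %||% tempdir(), "spots")
  spot_paths <- gen_spot_tables(ex$matrix, spot_dir,
                                bias_coef = sy$bias_coef,
                                missing_rate = sy$missing_rate,
                                seed = seed + 1L)

  ## stage: arrayio ------------------------------------------------------
  spots <- lapply(spot_paths, read_spot_table)
  ratios <- lapply(spots, lowess_normalize, span = th$span)
  em <- build_matrix(ratios, ex$matrix$classes,
                     spot_ids = spots[[1]]$spot_id,
                     gene_annot = spots[[1]]$gene_id,
                     max_missing = th$max_missing,
                     sample_ids = names(spot_paths))

  ## stage: SAM, 3-class pre-filter then 2-class ------------------------
  sc3 <- compute_scores(em, design = "multiclass")
  sc3 <- estimate_fdr(sc3, n_perm = th$n_perm, seed = seed + 2L)
  pre <- select_significant(sc3, th$q_sam_3class)
  # two-class statistic and its permutation null are computed on the whole
  # array (a signal-rich subset would contaminate the null); the selection
  # is then intersected with the multiclass prefilter survivors
  sc2 <- compute_scores(em, design = "twoclass",
                        class_pair = c("E2", "control"))
  sc2 <- estimate_fdr(sc2, n_perm = th$n_perm, seed = seed + 3L)
  cand2 <- select_significant(sc2, th$q_sam_2class)
  cand <- list(up = intersect(cand2$up, pre$selected),
               down = intersect(cand2$down, pre$selected),
               selected = intersect(cand2$selected, pre$selected))

  ## stage: responsive classification -----------------------------------
  resp <- classify_response(em, cand, min_fold = th$min_fold,
                            tau = th$tau)
  emit(resp, "responsive_genes.tsv")

  ## stage: genome, homology, cell lines --------------------------------
  gen <- gen_genome_and_loci(
    n_chrom = sy$n_chrom, chrom_len = sy$chrom_len,
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

  ## stage: homolog mapping and conservation ----------------------------
  mp <- map_to_human(resp$gene_id, reg$homology)
  universe <- reg$universe
  per_line <- lapply(reg$cell_lines, function(b)
    overlap_test(mp$human_ids, intersect(b, universe), universe))
  pooled_b <- sort(unique(intersect(unlist(reg$cell_lines), universe)))
  pooled <- overlap_test(mp$human_ids, pooled_b, universe)
  conserved_h <- intersect(mp$human_ids, pooled_b)
  nonconserved_h <- setdiff(mp$human_ids, pooled_b)
  emit(data.frame(gene_id = conserved_h), "conserved_genes.tsv")

  ## stage: regulome -----------------------------------------------------
  hits <- scan_motif(gen$genome)
  loci_cons <- gen$loci[gen$loci$gene_id %in% conserved_h, , drop = FALSE]
  motif_res <- NULL
  if (nrow(loci_cons) > 0 && nrow(hits) > 0) {
    flanks <- extract_flanks(loci_cons, flank = sy$flank,
                             chrom_lengths = gen$chrom_lengths)
    motif_res <- motif_enrichment(hits, flanks,
                                  genome_size = sum(gen$chrom_lengths))
  }
  site_res <- NULL
  noncons_rate <- NA_real_
  if (length(conserved_h) > 0) {
    site_res <- site_enrichment(
      intersect(conserved_h, gen$loci$gene_id), gen$loci, reg$sites,
      window = sy$window, n_rand = th$n_rand, seed = seed + 6L)
    nc <- intersect(nonconserved_h, gen$loci$gene_id)
    if (length(nc)) {
      asg <- assign_sites(gen$loci[gen$loci$gene_id %in% nc, ],
                          reg$sites, window = sy$window)
      noncons_rate <- trunc2(asg$total / length(nc))
    }
  }

  ## stage: gene-set enrichment -----------------------------------------
  annotations <- c(
    list(planted_conserved = reg$truth$conserved_human),
    local({
      set.seed(seed + 7L)
      stats::setNames(lapply(1:5, function(i)
        sample(universe, min(60, length(universe)))),
        sprintf("random_set_%d", 1:5))
    }))
  enr <- fisher_enrichment(conserved_h, annotations, universe)
  emit(enr, "enrichment.tsv")

  ## truth-based evaluation ----------------------------------------------
  truth_cons <- reg$truth$conserved_fish
  found_fish <- resp$gene_id[resp$gene_id %in%
                               reg$homology$source_id[
                                 reg$homology$target_id %in% conserved_h]]
  recall_conserved <- if (length(truth_cons))
    length(intersect(truth_cons, found_fish)) / length(truth_cons)
    else NA_real_
  recall_responsive <-
    length(intersect(ex$truth$planted$gene_id, resp$gene_id)) /
    max(1, nrow(ex$truth$planted))

  report <- list(
    seed = seed,
    version = as.character(utils::packageVersion("estrocon")),
    thresholds = th,
    counts = list(
      n_total = nrow(em$values),
      n_dropped_missing = attr(em, "n_dropped"),
      n_prefilter = length(pre$selected),
      n_up = sum(resp$direction == "up"),
      n_down = sum(resp$direction == "down"),
      n_responsive = nrow(resp),
      n_normalized = sum(resp$rescue == "normalized"),
      n_partial = sum(resp$rescue == "partial")
    ),
    homology = list(
      n_input = mp$n_input, n_mapped = mp$n_mapped,
      n_human = length(mp$human_ids),
      mapping_rate = mp$mapping_rate,
      mapping_rate_percent = round(100 * mp$mapping_rate, 1)
    ),
    conservation = c(
      list(n_conserved = length(conserved_h),
           n_nonconserved = length(nonconserved_h),
           percent_of_mapped = round(100 * length(conserved_h) /
                                       max(1, length(mp$human_ids)))),
      list(pooled = pooled[c("overlap_k", "percent_overlap",
                             "p_binomial", "p_hypergeometric")],
           per_cell_line = lapply(per_line, function(o)
             o[c("overlap_k", "percent_overlap", "p_binomial",
                 "p_hypergeometric")]))
    ),
    regulome = list(
      motif = motif_res,
      sites = site_res,
      genes_with_site = site_res$genes_with_site %||% NA,
      sites_per_gene_conserved = site_res$per_gene_rate %||% NA,
      sites_per_gene_nonconserved = noncons_rate
    ),
    enrichment_top = utils::head(enr, 3),
    truth_eval = list(
      recall_responsive = recall_responsive,
      recall_conserved = recall_conserved,
      n_planted = nrow(ex$truth$planted),
      n_planted_conserved = length(truth_cons)
    )
  )
  if (!is.null(out)) {
    write_sam_scores(sc2, file.path(out, "sam_twoclass.tsv"))
    write_json_report(report, file.path(out, "report.json"))
  }
  invisible(report)
}
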