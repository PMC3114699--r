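#' Generate a three-class expression matrix with planted responsive genes
#'
#' Emulates the study design: a two-channel array experiment with 4 vehicle
#' controls, 3 E2-treated and 3 E2+ICI-treated samples.  Null genes are
#' i.i.d. Normal(0, sigma) log2 ratios in every class.  Planted genes are
#' shifted in the E2 class by +/- log2(f) with f log-uniform on
#' `fold_range` (default [2, 128], the observed span of transcript-abundance
#' changes); in the E2+ICI class the shift is scaled by a rescue factor r:
#' r = 0.1 for genes planted as `normalized` (anti-estrogen restores
#' near-control expression) and r = 0.6 for `partial` suppression.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_per_class samples per class `(control, E2, E2_ICI)`,
#'   default `c(4, 3, 3)`.
#' @param n_planted number of planted responsive genes.
#' @param sigma log2-scale noise standard deviation (default 0.5).
#' @param rescue_fraction fraction of planted genes with `normalized`
#'   rescue (default 0.5).
#' @param fold_range linear fold-change range for planting (log-uniform).
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (`SynthTruth`): data.frame `planted` (`gene_id`, `direction`, `fold`,
#'   `rescue`), vectors `planted_up` / `planted_down`, and `seed`.
#' @export
gen_expression <- function(n_genes = 2000, n_per_class = c(4, 3, 3),
                           n_planted = 100, sigma = 0.5,
                           rescue_fraction = 0.5, fold_range = c(2, 128),
                           seed = 1) {
  if (length(n_per_class) != 3 || any(n_per_class < 2))
    stop_cls("estrocon_design_error",
             "n_per_class must be three counts >= 2")
  if (n_planted >= n_genes)
    stop_cls("estrocon_design_error", "n_planted must be < n_genes")
  set.seed(seed)
  n <- sum(n_per_class)
  classes <- rep(c("control", "E2", "E2_ICI"), n_per_class)
  vals <- matrix(stats::rnorm(n_genes * n, 0, sigma), n_genes, n)
  ids <- sprintf("f%05d", seq_len(n_genes))
  rownames(vals) <- ids
  colnames(vals) <- sprintf("%s_%d", classes,
                            unlist(lapply(n_per_class, seq_len)))
  planted <- if (n_planted > 0) sort(sample.int(n_genes, n_planted))
             else integer(0)
  truth <- data.frame(gene_id = character(0), direction = character(0),
                      fold = numeric(0), rescue = character(0),
                      stringsAsFactors = FALSE)
  if (n_planted > 0) {
    sgn <- sample(c(1, -1), n_planted, replace = TRUE)
    lfc <- stats::runif(n_planted, log2(fold_range[1]), log2(fold_range[2]))
    rescue <- ifelse(stats::runif(n_planted) < rescue_fraction,
                     "normalized", "partial")
    r <- ifelse(rescue == "normalized", 0.1, 0.6)
    e2_cols <- which(classes == "E2")
    ici_cols <- which(classes == "E2_ICI")
    vals[planted, e2_cols] <- vals[planted, e2_cols] + sgn * lfc
    vals[planted, ici_cols] <- vals[planted, ici_cols] + r * sgn * lfc
    truth <- data.frame(
      gene_id = ids[planted],
      direction = ifelse(sgn > 0, "up", "down"),
      fold = 2^lfc, rescue = rescue, stringsAsFactors = FALSE)
  }
  list(
    matrix = expression_matrix(vals, classes),
    truth = list(planted = truth,
                 planted_up = truth$gene_id[truth$direction == "up"],
                 planted_down = truth$gene_id[truth$direction == "down"],
                 seed = seed)
  )
}

#' Write GenePix-style spot tables realizing a true log2-ratio matrix
#'
#' Converts each column of a true probe x sample log2-ratio matrix into a
#' two-channel spot table: per-spot mean log intensity A ~ Uniform(8, 14),
#' an intensity-dependent dye bias `bias_coef * (A - 11)` added to M, and
#' foreground/background intensities reconstructed so that
#' log2(net_cy5/net_cy3) = M + bias.  A fraction of spots is flagged bad.
#' Reading these tables back through [read_spot_table()] and
#' [lowess_normalize()] recovers the true ratios up to the smoother's
#' residual error.
#'
#' @param em an [expression_matrix()] holding the true ratios.
#' @param dir output directory (created); one `<sample>.tsv` per column.
#' @param bias_coef slope of the planted intensity-dependent dye bias in
#'   log2 units per log2-intensity unit (default 0.2).
#' @param missing_rate fraction of spots flagged bad per array.
#' @param seed integer seed.
#' @return character vector of file paths, named by sample id.
#' @export
gen_spot_tables <- function(em, dir, bias_coef = 0.2, missing_rate = 0.01,
                            seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_g <- nrow(em$values)
  paths <- character(0)
  for (j in seq_len(ncol(em$values))) {
    A <- stats::runif(n_g, 8, 14)
    M <- em$values[, j] + bias_coef * (A - 11)
    f5 <- 2^(A + M / 2)
    f3 <- 2^(A - M / 2)
    df <- data.frame(
      ID = rownames(em$values), Name = rownames(em$values),
      F635 = round(f5 + 40, 2), B635 = 40,
      F532 = round(f3 + 40, 2), B532 = 40,
      Flags = ifelse(stats::runif(n_g) < missing_rate, -50L, 100L)
    )
    p <- file.path(dir, paste0(colnames(em$values)[j], ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[colnames(em$values)[j]] <- p
  }
  paths
}

#' Generate a random genome with gene loci and planted consensus motifs
#'
#' Chromosome sequences are i.i.d. bases at the requested GC content.
#' Genes are placed non-overlapping, evenly spread (one random offset per
#' slot).  Motif instances (degenerate positions resolved to random bases)
#' are planted (a) uniformly genome-wide at `background_motif_rate`
#' expected instances per 100 kb, and (b) inside the flanks of designated
#' genes at `planted_motif_rate_in_flanks` expected instances per flank.
#' Plants never overlap one another, so every recorded position is
#' recoverable by [scan_motif()].
#'
#' @param n_chrom,chrom_len number and length (bp) of chromosomes.
#' @param n_genes number of gene loci.
#' @param gc GC fraction (default 0.5).
#' @param motif IUPAC consensus to plant (default the ERE).
#' @param motif_genes gene ids receiving flank plants (default none).
#' @param planted_motif_rate_in_flanks expected plants per flank for
#'   designated genes.
#' @param background_motif_rate expected plants per 100 kb genome-wide.
#' @param flank flank width for planting (bp).
#' @param gene_length length of each gene locus (bp).
#' @param id_prefix prefix for generated gene ids.
#' @param seed integer seed.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `loci`
#'   (data.frame `gene_id`/`chrom`/`start`/`end`/`strand`),
#'   `chrom_lengths` (named vector), and `truth` holding
#'   `planted_motif_positions` (data.frame `chrom`/`pos`/`in_flank`/
#'   `gene_id`) and `seed`.
#' @export
gen_genome_and_loci <- function(n_chrom = 2, chrom_len = 1e6,
                                n_genes = 100, gc = 0.5,
                                motif = "GGTCAnnnTGACC",
                                motif_genes = character(0),
                                planted_motif_rate_in_flanks = 0,
                                background_motif_rate = 0,
                                flank = 20000, gene_length = 5000,
                                id_prefix = "h", seed = 1) {
  set.seed(seed)
  motif <- toupper(motif)
  mlen <- nchar(motif)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  seqs <- lapply(seq_len(n_chrom), function(i)
    sample(names(base_p), chrom_len, replace = TRUE, prob = base_p))
  names(seqs) <- chroms

  # even split of genes over chromosomes, one per slot
  per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  loci <- list()
  gi <- 0L
  for (i in seq_len(n_chrom)) {
    if (per[i] == 0) next
    slot <- floor(chrom_len / per[i])
    if (slot < gene_length + 2 * mlen)
      stop_cls("estrocon_packing_error",
               "cannot pack ", per[i], " genes of ", gene_length,
               " bp into ", chrom_len, " bp")
    off <- floor(stats::runif(per[i], 0, slot - gene_length))
    start <- (seq_len(per[i]) - 1L) * slot + off
    loci[[i]] <- data.frame(
      gene_id = sprintf("%s%05d", id_prefix, gi + seq_len(per[i])),
      chrom = chroms[i], start = as.integer(start),
      end = as.integer(start + gene_length),
      strand = sample(c("+", "-"), per[i], replace = TRUE),
      stringsAsFactors = FALSE)
    gi <- gi + per[i]
  }
  loci <- do.call(rbind, loci)

  occupied <- stats::setNames(vector("list", n_chrom), chroms)
  plants <- list()
  plant_one <- function(chrom, lo, hi, in_flank, gene_id) {
    # plant start uniform on [lo, hi - mlen); avoid overlapping other plants
    for (try in 1:200) {
      pos <- floor(stats::runif(1, lo, hi - mlen))
      occ <- occupied[[chrom]]
      if (is.null(occ) || all(abs(occ - pos) >= mlen)) {
        occupied[[chrom]] <<- c(occ, pos)
        inst <- vapply(strsplit(motif, "")[[1]], function(ch) {
          opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
          if (length(opts) == 1) opts else sample(opts, 1)
        }, "")
        seqs[[chrom]][(pos + 1):(pos + mlen)] <<- inst
        plants[[length(plants) + 1]] <<- data.frame(
          chrom = chrom, pos = as.integer(pos), in_flank = in_flank,
          gene_id = gene_id, stringsAsFactors = FALSE)
        return(TRUE)
      }
    }
    stop_cls("estrocon_packing_error", "could not place motif plant")
  }
  if (background_motif_rate > 0) {
    for (chrom in chroms) {
      n_bg <- stats::rpois(1, background_motif_rate * chrom_len / 1e5)
      for (k in seq_len(n_bg))
        plant_one(chrom, 0, chrom_len, FALSE, NA_character_)
    }
  }
  if (planted_motif_rate_in_flanks > 0 && length(motif_genes)) {
    for (g in motif_genes) {
      row <- loci[loci$gene_id == g, ]
      if (nrow(row) != 1)
        stop_cls("estrocon_membership_error", "unknown motif gene: ", g)
      fl <- list(c(max(0, row$start - flank), row$start),
                 c(row$end, min(chrom_len, row$end + flank)))
      for (side in fl) {
        n_p <- stats::rpois(1, planted_motif_rate_in_flanks)
        for (k in seq_len(n_p))
          if (side[2] - side[1] > 2 * mlen)
            plant_one(row$chrom, side[1], side[2], TRUE, g)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms
  plants_df <- if (length(plants)) do.call(rbind, plants)
               else data.frame(chrom = character(0), pos = integer(0),
                               in_flank = logical(0),
                               gene_id = character(0))
  list(genome = genome, loci = loci,
       chrom_lengths = stats::setNames(rep(chrom_len, n_chrom), chroms),
       truth = list(planted_motif_positions = plants_df, seed = seed))
}

#' Generate binding sites, a homology map, and cell-line gene lists
#'
#' Completes the synthetic study inputs around a set of (human-side) gene
#' loci: (i) a homology map in which each source-species gene maps with
#' probability `homolog_rate` to a human gene drawn from the loci (with a
#' `many_to_one` fraction of sources re-using an already-assigned target);
#' (ii) binding sites placed uniformly over the genome except for an
#' `enrich_factor`-fold density inside the `window`-neighbourhoods of the
#' designated conserved genes; (iii) cell-line estrogen-responsive gene
#' lists constructed so each conserved gene appears in at least one list
#' and overall list membership hits the target sizes.
#'
#' @param loci human gene loci (from [gen_genome_and_loci()]).
#' @param chrom_lengths named chromosome lengths.
#' @param source_ids source-species (e.g. zebrafish) gene universe.
#' @param responsive_ids subset of `source_ids` that is estrogen-responsive.
#' @param conserved_candidates subset of `responsive_ids` eligible to be
#'   planted as conserved (default: all of them).  The pipeline passes the
#'   robust responders here, emulating the observation that genes conserved
#'   across species and platforms are the strongly responding core, not the
#'   ones at the detection floor.
#' @param n_sites number of binding sites (default 500).
#' @param enrich_factor site-density multiplier inside conserved-gene
#'   windows (default 1 = uniform).
#' @param target_genes human gene ids to treat as conserved; by default
#'   drawn from the mapped responsive set, each with probability
#'   `overlap_fraction`.
#' @param window neighbourhood half-width (bp) for enrichment planting.
#' @param site_width binding-site width (bp).
#' @param homolog_rate fraction of source genes with a human homolog
#'   (default 0.435, the rate observed for the zebrafish array).
#' @param many_to_one fraction of mapped sources re-using an existing
#'   target.
#' @param n_cell_lines number of cell-line lists (default 4).
#' @param cell_line_frac list size as a fraction of the human universe.
#' @param overlap_fraction expected fraction of the mapped responsive set
#'   found in at least one cell-line list (default 0.29).
#' @param seed integer seed.
#' @return list with `sites` (data.frame), `homology` (data.frame
#'   `source_id`/`target_id`), `cell_lines` (named list of id vectors),
#'   `universe` (human ids with loci), and `truth` (conserved fish/human
#'   ids, seed).
#' @export
gen_regulome_and_sets <- function(loci, chrom_lengths, source_ids,
                                  responsive_ids,
                                  conserved_candidates = responsive_ids,
                                  n_sites = 500, enrich_factor = 1,
                                  target_genes = NULL, window = 5000,
                                  site_width = 200,
                                  homolog_rate = 0.435, many_to_one = 0.1,
                                  n_cell_lines = 4, cell_line_frac = 0.18,
                                  overlap_fraction = 0.29, seed = 1) {
  if (enrich_factor < 1)
    stop_cls("estrocon_design_error", "enrich_factor must be >= 1")
  if (overlap_fraction > 1)
    stop_cls("estrocon_design_error", "overlap_fraction must be <= 1")
  set.seed(seed)
  human_ids <- loci$gene_id

  # homology: mapped sources get targets sampled without replacement until
  # exhausted; a many_to_one fraction re-uses an already-used target
  mapped <- source_ids[stats::runif(length(source_ids)) < homolog_rate]
  n_m <- length(mapped)
  fresh_pool <- sample(human_ids)
  targets <- character(n_m)
  used <- character(0)
  fi <- 1L
  for (i in seq_len(n_m)) {
    reuse <- length(used) > 0 &&
      (stats::runif(1) < many_to_one || fi > length(fresh_pool))
    if (reuse) {
      targets[i] <- sample(used, 1)
    } else {
      targets[i] <- fresh_pool[fi]
      fi <- fi + 1L
      used <- c(used, targets[i])
    }
  }
  homology <- data.frame(source_id = mapped, target_id = targets,
                         stringsAsFactors = FALSE)

  resp_h <- unique(targets[mapped %in% responsive_ids])
  cand_h <- unique(targets[mapped %in% conserved_candidates])
  if (is.null(target_genes)) {
    conserved_h <- cand_h[stats::runif(length(cand_h)) < overlap_fraction]
  } else {
    conserved_h <- intersect(target_genes, human_ids)
  }
  conserved_fish <- homology$source_id[homology$target_id %in% conserved_h &
                                         homology$source_id %in%
                                           responsive_ids]

  # binding sites: weighted uniform/enriched placement
  tgt_loci <- loci[loci$gene_id %in% conserved_h, , drop = FALSE]
  G <- sum(chrom_lengths)
  if (nrow(tgt_loci) > 0 && enrich_factor > 1) {
    win <- GenomicRanges::reduce(as_granges0(data.frame(
      chrom = tgt_loci$chrom,
      start = pmax(0, tgt_loci$start - window),
      end = pmin(chrom_lengths[tgt_loci$chrom], tgt_loci$end + window))))
    w_in <- sum(BiocGenerics::width(win))
    p_in <- enrich_factor * w_in / (enrich_factor * w_in + (G - w_in))
  } else {
    win <- NULL
    w_in <- 0
    p_in <- 0
  }
  site_pos <- function(n, inside) {
    if (n == 0)
      return(data.frame(chrom = character(0), start = integer(0)))
    if (inside) {
      st <- BiocGenerics::start(win) - 1L
      wd <- BiocGenerics::width(win)
      iv <- sample.int(length(win), n, replace = TRUE, prob = wd)
      pos <- st[iv] + floor(stats::runif(n) * wd[iv])
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(win))[iv],
                 start = as.integer(pos))
    } else {
      # uniform over the genome (complement not carved out: at the default
      # scale the windows are a small fraction, and enriched mass dominates)
      ch <- sample(names(chrom_lengths), n, replace = TRUE,
                   prob = chrom_lengths)
      data.frame(chrom = ch,
                 start = as.integer(floor(stats::runif(n) *
                                            (chrom_lengths[ch] -
                                               site_width))))
    }
  }
  n_in <- stats::rbinom(1, n_sites, p_in)
  pos <- rbind(site_pos(n_in, TRUE), site_pos(n_sites - n_in, FALSE))
  sites <- data.frame(chrom = pos$chrom, start = pos$start,
                      end = pmin(pos$start + site_width,
                                 chrom_lengths[pos$chrom]),
                      source = "synthetic", stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), ]
  rownames(sites) <- NULL

  # cell-line lists: each conserved gene goes into >= 1 list; lists are
  # padded with non-responsive universe genes up to the target size
  list_size <- max(1L, round(cell_line_frac * length(human_ids)))
  cl <- stats::setNames(vector("list", n_cell_lines),
                        sprintf("cellline_%d", seq_len(n_cell_lines)))
  for (nm in names(cl)) cl[[nm]] <- character(0)
  for (g in conserved_h) {
    k <- 1 + stats::rbinom(1, n_cell_lines - 1, 0.2)
    for (nm in sample(names(cl), k)) cl[[nm]] <- c(cl[[nm]], g)
  }
  pad_pool <- setdiff(human_ids, resp_h)
  for (nm in names(cl)) {
    need <- list_size - length(cl[[nm]])
    if (need > 0)
      cl[[nm]] <- c(cl[[nm]], sample(pad_pool, min(need,
                                                   length(pad_pool))))
    cl[[nm]] <- sort(unique(cl[[nm]]))
  }

  list(
    sites = sites, homology = homology, cell_lines = cl,
    universe = sort(unique(homology$target_id)),
    truth = list(conserved_human = sort(conserved_h),
                 conserved_fish = sort(unique(conserved_fish)),
                 mapped_responsive_human = sort(resp_h),
                 seed = seed)
  )
}

#' Write the synthetic inputs in the pipeline's external formats
#'
#' FASTA genome, BED loci and sites, two-column homology TSV, one-id-per-
#' line cell-line lists, and a truth JSON.
#'
#' @param synth list combining outputs of [gen_genome_and_loci()] and
#'   [gen_regulome_and_sets()].
#' @param dir output directory (created).
#' @return named character vector of written paths.
#' @export
write_synth_inputs <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             loci = file.path(dir, "loci.bed"),
             sites = file.path(dir, "sites.bed"),
             homology = file.path(dir, "homology.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(synth$genome, paths["genome"])
  write_bed(synth$loci, paths["loci"])
  write_bed(synth$sites, paths["sites"])
  utils::write.table(synth$homology, paths["homology"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(synth$cell_lines)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(synth$cell_lines[[nm]], p)
    paths[nm] <- p
  }
  jsonlite::write_json(synth$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths
}
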