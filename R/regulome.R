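#' Scan a genome for a degenerate (IUPAC) consensus motif
#'
#' Finds every exact match to the consensus on both strands.  The default
#' estrogen response element, GGTCAnnnTGACC, is its own reverse complement,
#' so every genomic position harbours the motif on both strands at once; in
#' that case each position is reported once with strand `+`.  Coordinates
#' are 0-based.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param pattern IUPAC consensus string (length >= 4).
#' @return data.frame (`MotifHit` rows): `chrom`, `pos` (0-based start),
#'   `strand`, `matched` (the matched genomic substring, forward strand).
#' @export
scan_motif <- function(genome, pattern = "GGTCAnnnTGACC") {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4)
    stop_cls("estrocon_pattern_error", "pattern too short (< 4)")
  if (!all(strsplit(pattern, "")[[1]] %in%
           names(Biostrings::IUPAC_CODE_MAP)))
    stop_cls("estrocon_pattern_error",
             "invalid IUPAC character in pattern: ", pattern)
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(pat) == as.character(rc)
  # strip FASTA description from names
  nms <- sub("\\s.*$", "", names(genome) %||%
               sprintf("chr%d", seq_along(genome)))
  res <- list()
  for (i in seq_along(genome)) {
    subj <- genome[[i]]
    hit_f <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    if (length(hit_f))
      res[[length(res) + 1]] <- data.frame(
        chrom = nms[i], pos = BiocGenerics::start(hit_f) - 1L,
        strand = "+",
        matched = as.character(hit_f), stringsAsFactors = FALSE)
    if (!palindromic) {
      hit_r <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
      if (length(hit_r))
        res[[length(res) + 1]] <- data.frame(
          chrom = nms[i], pos = BiocGenerics::start(hit_r) - 1L,
          strand = "-",
          matched = as.character(hit_r), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), matched = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Flanking-plus-body regions around gene loci
#'
#' For each gene returns the union of a 5' flank, the gene body, and a 3'
#' flank — i.e. the interval `[start - flank, end + flank)` clipped to the
#' chromosome — the neighbourhood scanned for regulatory motifs.  Strand is
#' used only to label which flank is 5' vs 3'.
#'
#' @param loci data.frame (`GeneLocus` rows): `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param flank flank width in bp (default 20000).
#' @param chrom_lengths named integer vector of chromosome lengths; when
#'   omitted, no right clipping is done.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (clipped).
#' @export
extract_flanks <- function(loci, flank = 20000, chrom_lengths = NULL) {
  start <- pmax(0, loci$start - flank)
  end <- loci$end + flank
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[loci$chrom]
    if (anyNA(len))
      stop_cls("estrocon_design_error", "loci on unknown chromosomes")
    if (any(loci$end > len))
      warning("loci extend past chromosome end; clipped")
    end <- pmin(end, len)
  }
  data.frame(gene_id = loci$gene_id, chrom = loci$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Motif enrichment in regions vs the genome-wide distribution
#'
#' Tests whether motif hits concentrate inside a region set: with `n` hits
#' genome-wide and the (merged) regions covering a fraction `w` of the
#' genome, the observed in-region count is compared to
#' `X ~ Binomial(n, w)`, one-sided.
#'
#' @param hits data.frame from [scan_motif()].
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); overlapping regions are merged before computing coverage.
#' @param genome_size total genome length in bp.
#' @return list (`EnrichmentResult`): `observed`, `expected`, `ratio`,
#'   `p_binomial`, `region_width`, `genome_size`, `n_hits_total`, `null`.
#' @export
motif_enrichment <- function(hits, regions, genome_size) {
  n <- nrow(hits)
  if (n == 0)
    stop_cls("estrocon_undefined_test", "no motif hits genome-wide")
  reg <- GenomicRanges::reduce(as_granges0(regions))
  width <- sum(BiocGenerics::width(reg))
  if (width <= 0 || width > genome_size)
    stop_cls("estrocon_design_error",
             "need 0 < region width <= genome_size")
  pts <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$pos + 1L, width = 1))
  observed <- sum(IRanges::overlapsAny(pts, reg))
  p <- width / genome_size
  expected <- n * p
  list(
    observed = observed, expected = expected,
    ratio = observed / expected,
    p_binomial = stats::pbinom(observed - 1, n, p, lower.tail = FALSE),
    region_width = width, genome_size = genome_size, n_hits_total = n,
    null = sprintf("Binomial(%d, %.6g): uniform hits over the genome",
                   n, p)
  )
}

#' Count binding sites in a window around each gene
#'
#' A site is counted for a gene when its interval overlaps
#' `[start - window, end + window)`.  Windows of neighbouring genes are not
#' merged: a site near two genes counts for both, matching per-gene
#' "sites per gene" arithmetic.
#'
#' @param loci data.frame of gene loci (see [extract_flanks()]).
#' @param sites data.frame (`BindingSite` rows): `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window neighbourhood half-width in bp (default 100000).
#' @return list with `counts` (named integer vector per gene),
#'   `genes_with_site` (ids with >= 1 site), `total` (sum of counts).
#' @export
assign_sites <- function(loci, sites, window = 100000) {
  win <- data.frame(chrom = loci$chrom,
                    start = pmax(0, loci$start - window),
                    end = loci$end + window)
  counts <- GenomicRanges::countOverlaps(as_granges0(win),
                                         as_granges0(sites))
  names(counts) <- loci$gene_id
  list(counts = counts,
       genes_with_site = loci$gene_id[counts > 0],
       total = sum(counts))
}

#' Binding-site enrichment in a target gene set, with a randomization null
#'
#' Compares the total number of binding sites within `window` of the target
#' genes to (i) an empirical null built by repeatedly drawing the same
#' number of genes at random from the background locus collection and
#' recounting, and (ii) a binomial null in which each of the site-to-gene
#' assignments observed over the whole background falls on a target gene
#' with probability `|targets| / |background|`.
#'
#' @param target_ids character vector of target gene ids (must appear in
#'   `background_loci$gene_id`).
#' @param background_loci data.frame of all candidate gene loci.
#' @param sites data.frame of binding sites.
#' @param window neighbourhood half-width in bp (default 100000).
#' @param n_rand number of random gene draws (default 1000).
#' @param seed integer seed.
#' @return list (`EnrichmentResult`): `observed`, `expected` (null mean),
#'   `expected_analytic` (binomial mean), `per_gene_rate` (observed /
#'   targets, truncated to 2 decimals), `p_empirical`
#'   (`(1 + #null >= obs) / (n_rand + 1)`), `p_binomial`, `null_sd`,
#'   `n_randomizations`, `n_targets`, `genes_with_site`, `null`.
#' @export
site_enrichment <- function(target_ids, background_loci, sites,
                            window = 100000, n_rand = 1000, seed = 1) {
  target_ids <- unique(as.character(target_ids))
  bg_ids <- background_loci$gene_id
  if (!all(target_ids %in% bg_ids))
    stop_cls("estrocon_membership_error",
             "target genes missing from background loci: ",
             paste(utils::head(setdiff(target_ids, bg_ids), 5),
                   collapse = ", "))
  n_t <- length(target_ids)
  if (length(bg_ids) < n_t)
    stop_cls("estrocon_sampling_error",
             "background smaller than target set")
  asg <- assign_sites(background_loci, sites, window)
  counts <- asg$counts
  observed <- sum(counts[target_ids])
  set.seed(seed)
  null <- vapply(seq_len(n_rand), function(i)
    sum(counts[sample.int(length(counts), n_t)]), 1.0)
  total_assign <- sum(counts)
  p <- n_t / length(bg_ids)
  list(
    observed = observed,
    expected = mean(null),
    expected_analytic = total_assign * p,
    per_gene_rate = trunc2(observed / n_t),
    p_empirical = (1 + sum(null >= observed)) / (n_rand + 1),
    p_binomial = stats::pbinom(observed - 1, total_assign, p,
                               lower.tail = FALSE),
    null_sd = stats::sd(null),
    n_randomizations = n_rand,
    n_targets = n_t,
    genes_with_site = sum(counts[target_ids] > 0),
    null = sprintf(
      "%d draws of %d genes from %d background loci (seed %d)",
      n_rand, n_t, length(bg_ids), seed)
  )
}

#' Read gene loci or binding sites from a BED file
#'
#' Accepts 3-column (`chrom start end`) or 6-column
#' (`... name score strand`) BED.  BED is already 0-based half-open, so
#' coordinates are taken as-is.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `gene_id` and `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "gene_id"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df
}

#' Write intervals as BED (0-based half-open, as stored)
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `gene_id`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- df[, c("chrom", "start", "end")]
  if ("gene_id" %in% names(df)) {
    cols$name <- df$gene_id
    cols$score <- 0L
    cols$strand <- if ("strand" %in% names(df)) df$strand else "+"
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
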