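#' Read a two-column homology map
#'
#' @param path TSV with columns `source_id`, `target_id` (header optional;
#'   detected by whether the first row looks like those names).
#' @return data.frame with `source_id`, `target_id`.
#' @export
read_homology_map <- function(path) {
  first <- utils::read.delim(path, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  header <- identical(tolower(as.character(first[1, 1])), "source_id")
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("source_id", "target_id")
  df[, 1:2]
}

#' Map gene identifiers to homologs in another species
#'
#' Each source identifier maps to at most one target (when the raw map is
#' one-to-many, the lexicographically first target is kept, so mapping is
#' deterministic); many sources may share a target, and the returned target
#' set is deduplicated, since downstream set intersections must live on a
#' single namespace.
#'
#' @param gene_ids character vector of source-species gene identifiers.
#' @param map data.frame with columns `source_id`, `target_id`.
#' @return list with `human_ids` (unique mapped targets), `mapping_rate`
#'   (fraction of inputs with a homolog; 0 with `rate_defined = FALSE` for
#'   empty input), `unmapped` (inputs without a homolog), `n_input`,
#'   `n_mapped`.
#' @export
map_to_human <- function(gene_ids, map) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0)
    return(list(human_ids = character(0), mapping_rate = 0,
                rate_defined = FALSE, unmapped = character(0),
                n_input = 0L, n_mapped = 0L))
  map <- map[order(map$source_id, map$target_id), ]
  map <- map[!duplicated(map$source_id), ]           # one target per source
  idx <- match(gene_ids, map$source_id)
  mapped <- !is.na(idx)
  list(
    human_ids = unique(map$target_id[idx[mapped]]),
    mapping_rate = sum(mapped) / length(gene_ids),
    rate_defined = TRUE,
    unmapped = gene_ids[!mapped],
    n_input = length(gene_ids),
    n_mapped = sum(mapped)
  )
}

#' Test the overlap of two gene sets against a common universe
#'
#' Computes the intersection size and one-sided enrichment p-values under
#' two nulls: binomial (`P(X >= k)`, `X ~ Binomial(|a|, |b|/N)`) — the test
#' the study design calls for — and the exact hypergeometric tail of the
#' 2x2 table.  `percent_overlap` uses the first-listed set as denominator.
#'
#' @param a,b character vectors (gene sets), both subsets of `universe`.
#' @param universe character vector, the background gene universe.
#' @return list (`OverlapResult`): `set_a_size`, `set_b_size`,
#'   `universe_size`, `overlap_k`, `percent_overlap`, `p_binomial`,
#'   `p_hypergeometric`, `saturated` (TRUE when a = b = universe).
#' @export
overlap_test <- function(a, b, universe) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  universe <- unique(as.character(universe))
  if (length(universe) == 0)
    stop_cls("estrocon_design_error", "empty universe")
  bad <- c(setdiff(a, universe), setdiff(b, universe))
  if (length(bad))
    stop_cls("estrocon_membership_error",
             "sets not contained in universe: ",
             paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) " ..." else "")
  N <- length(universe)
  k <- length(intersect(a, b))
  p_bin <- stats::pbinom(k - 1, size = length(a), prob = length(b) / N,
                         lower.tail = FALSE)
  p_hyp <- stats::phyper(k - 1, m = length(b), n = N - length(b),
                         k = length(a), lower.tail = FALSE)
  list(
    set_a_size = length(a), set_b_size = length(b), universe_size = N,
    overlap_k = k,
    percent_overlap = if (length(a)) k / length(a) else 0,
    p_binomial = p_bin,
    p_hypergeometric = p_hyp,
    saturated = (k == N && length(a) == N && length(b) == N)
  )
}

#' Region counts for a 2-4 set Venn diagram
#'
#' @param sets named list of 2-4 character vectors; names must be unique.
#' @return data.frame with one row per non-empty membership pattern:
#'   logical columns (one per set) and `count`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4)
    stop_cls("estrocon_design_error", "venn_counts takes 2-4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop_cls("estrocon_design_error", "sets must have unique labels")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_ids %in% s,
                 logical(length(all_ids)))
  if (length(all_ids) == 1) memb <- matrix(memb, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                              drop = FALSE]
  names(pat) <- names(sets)
  pat$count <- apply(pat, 1, function(p)
    sum(apply(memb, 1, function(row) all(row == p))))
  rownames(pat) <- NULL
  pat
}
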