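#' Right-tailed Fisher gene-set enrichment over an annotation table
#'
#' For each annotation category, tests whether the query gene set contains
#' more category members than expected under random sampling from the
#' universe — the upper (right) tail of the hypergeometric distribution for
#' the 2x2 table, i.e. a one-sided Fisher exact test.  Raw p-values are
#' always reported; Benjamini-Hochberg adjustment across categories is the
#' default and can be disabled.
#'
#' @param geneset character vector, the query set (subset of `universe`).
#' @param annotations named list: category id -> character vector of member
#'   gene ids.  Members outside the universe are ignored; categories with
#'   no member in the universe are skipped with a warning.
#' @param universe character vector, background universe.
#' @param adjust `"BH"` (default) or `"none"`.
#' @return data.frame (`EnrichmentRow`s) sorted by `p`: `category_id`,
#'   `k_in_set`, `set_size`, `k_in_universe`, `universe_size`, `p`,
#'   `p_adjusted`.
#' @export
fisher_enrichment <- function(geneset, annotations, universe,
                              adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe))
  geneset <- unique(as.character(geneset))
  if (!all(geneset %in% universe))
    stop_cls("estrocon_membership_error",
             "geneset not contained in universe")
  N <- length(universe)
  ns <- length(geneset)
  rows <- lapply(names(annotations), function(cat) {
    memb <- intersect(unique(as.character(annotations[[cat]])), universe)
    if (length(memb) == 0) {
      warning("category '", cat, "' has no members in universe; skipped")
      return(NULL)
    }
    k <- length(intersect(geneset, memb))
    p <- stats::phyper(k - 1, m = length(memb), n = N - length(memb),
                       k = ns, lower.tail = FALSE)
    data.frame(category_id = cat, k_in_set = k, set_size = ns,
               k_in_universe = length(memb), universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category_id = character(0), k_in_set = integer(0),
                      set_size = integer(0), k_in_universe = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      p_adjusted = numeric(0)))
  out$p_adjusted <- if (adjust == "BH") stats::p.adjust(out$p, "BH")
                    else out$p
  out <- out[order(out$p, out$category_id), ]
  rownames(out) <- NULL
  out
}

#' Read an annotation table from GMT or two-column TSV
#'
#' GMT: one category per line, `id <tab> description <tab> member...`.
#' Two-column TSV: `category_id <tab> gene_id`, one pair per line.
#'
#' @param path input path.
#' @param format `"gmt"` or `"tsv"`; guessed from the extension by default.
#' @return named list of character vectors.
#' @export
read_annotations <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv")
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(out) <- vapply(parts, `[`, "", 1)
    out
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            stringsAsFactors = FALSE)
    split(df[[2]], df[[1]])
  }
}
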