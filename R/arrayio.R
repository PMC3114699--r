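#' Default column dialect for GenePix-style spot tables
#'
#' Maps the fields the reader needs onto column names of the input file.
#' Defaults follow GenePix result (.gpr) conventions: Cy5 (F635/B635) is the
#' sample channel, Cy3 (F532/B532) the common reference.
#'
#' @param spot_id,gene_id,f_cy5,b_cy5,f_cy3,b_cy3,flag column names in the
#'   input file for each field.
#' @return named list usable as the `dialect` of [read_spot_table()].
#' @export
gpr_dialect <- function(spot_id = "ID", gene_id = "Name",
                        f_cy5 = "F635", b_cy5 = "B635",
                        f_cy3 = "F532", b_cy3 = "B532",
                        flag = "Flags") {
  list(spot_id = spot_id, gene_id = gene_id, f_cy5 = f_cy5, b_cy5 = b_cy5,
       f_cy3 = f_cy3, b_cy3 = b_cy3, flag = flag)
}

#' Read a spot-level two-channel intensity table
#'
#' Reads one array's worth of spot measurements (tab-separated, header row)
#' and computes net intensities as foreground minus local background in each
#' channel.  A spot is marked missing when its quality flag is nonpositive or
#' when the net intensity in either channel is nonpositive (the log-ratio is
#' undefined there).
#'
#' @param path path to the TSV file.
#' @param dialect column-name map, see [gpr_dialect()].
#' @return a `SpotTable`: data.frame with columns `spot_id`, `gene_id`,
#'   `net_cy5`, `net_cy3`, `flag`, `missing`.
#' @export
read_spot_table <- function(path, dialect = gpr_dialect()) {
  if (!file.exists(path))
    stop_cls("estrocon_io_error", "no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop_cls("estrocon_empty_input", "spot table is empty: ", path)
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (!col %in% names(df))
      stop_cls("estrocon_format_error",
               "spot table lacks mapped column '", col,
               "' (field ", field, "): ", path)
  }
  g <- function(f) df[[dialect[[f]]]]
  net_cy5 <- as.numeric(g("f_cy5")) - as.numeric(g("b_cy5"))
  net_cy3 <- as.numeric(g("f_cy3")) - as.numeric(g("b_cy3"))
  flag <- as.integer(g("flag"))
  out <- data.frame(
    spot_id = as.character(g("spot_id")),
    gene_id = as.character(g("gene_id")),
    net_cy5 = net_cy5, net_cy3 = net_cy3, flag = flag,
    missing = flag <= 0 | net_cy5 <= 0 | net_cy3 <= 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("SpotTable", "data.frame")
  out
}

#' Intensity-dependent (LOWESS) normalization of one array
#'
#' Computes per-spot M = log2(net_cy5/net_cy3) and
#' A = 0.5*log2(net_cy5*net_cy3), fits a locally weighted degree-1
#' regression of M on A (tricube weights, 3 robustness iterations), and
#' returns the bias-corrected ratios M - f(A).  Missing spots stay `NA`.
#'
#' @param spots a `SpotTable` from [read_spot_table()].
#' @param span LOWESS smoother span in (0, 1]; default 0.3.
#' @return numeric vector of normalized log2 ratios, one per spot row,
#'   `NA` where the spot is missing.
#' @export
lowess_normalize <- function(spots, span = 0.3) {
  stopifnot(span > 0, span <= 1)
  ok <- !spots$missing
  if (sum(ok) < 10)
    stop_cls("estrocon_insufficient_data",
             "need >= 10 non-missing spots, got ", sum(ok))
  M <- log2(spots$net_cy5[ok] / spots$net_cy3[ok])
  A <- 0.5 * log2(spots$net_cy5[ok] * spots$net_cy3[ok])
  fit <- stats::lowess(A, M, f = span, iter = 3)
  pred <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  out <- rep(NA_real_, nrow(spots))
  out[ok] <- M - pred
  out
}

#' Assemble per-array normalized ratios into an ExpressionMatrix
#'
#' Stacks per-array normalized log2 ratios (all arrays sharing one probe
#' list, in the same order) into a probe x sample matrix and drops probes
#' with more than `max_missing` missing values across samples.  Probes are
#' kept separate here even when several share a gene annotation; collapse to
#' gene level happens at reporting (most significant probe represents the
#' gene), avoiding averaging artifacts.
#'
#' @param ratios list of numeric vectors (one per array) of normalized
#'   ratios, `NA` = missing; equal lengths, same probe order.
#' @param classes per-array class labels.
#' @param spot_ids probe identifiers (length = probes).
#' @param gene_annot optional per-probe gene annotation.
#' @param max_missing maximum tolerated missing entries per probe
#'   (default 6); probes with strictly more are excluded.
#' @param sample_ids optional per-array names.
#' @return an [expression_matrix()] with attribute `n_dropped`, the number
#'   of probes removed by the missingness filter.
#' @export
build_matrix <- function(ratios, classes, spot_ids, gene_annot = NULL,
                         max_missing = 6, sample_ids = NULL) {
  lens <- vapply(ratios, length, 1L)
  if (length(unique(lens)) != 1L || lens[1] != length(spot_ids))
    stop_cls("estrocon_alignment_error",
             "arrays do not share the probe list (lengths ",
             paste(unique(c(lens, length(spot_ids))), collapse = ", "), ")")
  vals <- do.call(cbind, ratios)
  rownames(vals) <- spot_ids
  colnames(vals) <- sample_ids %||% sprintf("S%d", seq_along(ratios))
  keep <- rowSums(is.na(vals)) <= max_missing
  em <- expression_matrix(vals[keep, , drop = FALSE], classes,
                          gene_annot = gene_annot[keep])
  attr(em, "n_dropped") <- sum(!keep)
  em
}
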