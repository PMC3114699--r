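#' Gene-by-sample expression matrix with treatment classes
#'
#' Container for normalized log2(sample/reference) ratios from a set of
#' two-channel arrays, one column per array, together with the treatment
#' class of each array.  The default experimental design has three classes:
#' vehicle control, 17beta-estradiol (`E2`), and estradiol plus the pure
#' anti-estrogen ICI 182,780 (`E2_ICI`).  Entries may be `NA` (missing
#' spots).
#'
#' @param values numeric matrix, genes (probes) in rows, samples in columns.
#'   Row names are probe identifiers; column names are sample identifiers
#'   (generated as `S1..Sn` when absent).
#' @param classes character vector of per-sample class labels, one per
#'   column of `values`.
#' @param gene_annot optional character vector of gene identifiers, one per
#'   row (probe-level annotation; may contain `NA`/empty for unannotated
#'   probes).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `classes`, `gene_annot`.
#' @export
expression_matrix <- function(values, classes, gene_annot = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(classes) != ncol(values))
    stop_cls("estrocon_design_error",
             "length(classes) must equal ncol(values)")
  classes <- as.character(classes)
  if (anyNA(classes) || any(!nzchar(classes)))
    stop_cls("estrocon_design_error", "class labels must be non-empty")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe_%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  if (!is.null(gene_annot) && length(gene_annot) != nrow(values))
    stop_cls("estrocon_design_error",
             "gene_annot must have one entry per row")
  structure(
    list(values = values, classes = classes, gene_annot = gene_annot),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("classes:", paste(sprintf("%s(%d)", names(table(x$classes)),
                                table(x$classes)), collapse = " "), "\n")
  cat(sprintf("missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Write / read an ExpressionMatrix as TSV plus a JSON sidecar
#'
#' The TSV holds the genes x samples value matrix (`NA` for missing); the
#' sidecar `<path>.json` records sample classes and gene annotation so the
#' object round-trips.
#'
#' @param em an `ExpressionMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly (`write`); an `ExpressionMatrix` (`read`).
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(sample_ids = colnames(em$values), classes = em$classes,
               gene_annot = em$gene_annot, n_genes = nrow(em$values))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  ga <- side$gene_annot
  if (length(ga) == 0) ga <- NULL
  expression_matrix(vals, side$classes, gene_annot = ga)
}

# per-class column index list, in first-appearance order of labels
class_index <- function(em) {
  labs <- unique(em$classes)
  stats::setNames(lapply(labs, function(l) which(em$classes == l)), labs)
}
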