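#' Classify candidate genes as estrogen-responsive with a rescue label
#'
#' Applies the operational definition of "estrogen-responsive": a gene
#' significantly deregulated by E2 whose deregulation is suppressed when the
#' pure anti-estrogen ICI 182,780 is co-administered.  A candidate is kept
#' when (i) its E2 class mean is shifted from control in the candidate's
#' direction by at least `log2(min_fold)`, and (ii) the E2+ICI mean lies on
#' the control side of the E2 mean (up: mean(E2) > mean(control) and
#' mean(E2) > mean(E2_ICI); down: both reversed).  Kept genes are labelled
#' `normalized` when the residual E2+ICI shift from control is at most
#' `tau` times the E2 shift, else `partial`.
#'
#' @param em an [expression_matrix()] containing all three classes.
#' @param candidates list with character vectors `up` and `down` (e.g. from
#'   [select_significant()]).
#' @param min_fold minimum linear fold change of E2 vs control (default 2).
#' @param tau rescue fraction separating `normalized` from `partial`
#'   (default 0.25).
#' @param class_labels names of the control, E2 and E2+ICI classes in
#'   `em$classes`.
#' @return data.frame (`ResponsiveGene` rows): `gene_id`, `direction`,
#'   `mean_control`, `mean_e2`, `mean_e2_ici`, `fold_change_e2` (linear,
#'   >= 1), `rescue`.  Candidates absent from the matrix are reported in
#'   attribute `skipped`.
#' @export
classify_response <- function(em, candidates, min_fold = 2, tau = 0.25,
                              class_labels = c(control = "control",
                                               e2 = "E2",
                                               e2_ici = "E2_ICI")) {
  if (!all(class_labels %in% em$classes))
    stop_cls("estrocon_design_error",
             "matrix lacks classes: ",
             paste(setdiff(class_labels, em$classes), collapse = ", "))
  ids <- c(candidates$up, candidates$down)
  dirs <- rep(c("up", "down"), c(length(candidates$up),
                                 length(candidates$down)))
  present <- ids %in% rownames(em$values)
  skipped <- ids[!present]
  ids <- ids[present]; dirs <- dirs[present]

  m <- function(cl) rowMeans(
    em$values[ids, em$classes == class_labels[[cl]], drop = FALSE],
    na.rm = TRUE)
  mc <- m("control"); me <- m("e2"); mi <- m("e2_ici")

  shift_e2 <- me - mc
  shift_ici <- mi - mc
  sgn <- ifelse(dirs == "up", 1, -1)
  keep <- sgn * shift_e2 >= log2(min_fold) &   # direction + magnitude
    sgn * (me - mi) > 0                        # suppressed below E2
  rescue <- ifelse(abs(shift_ici) <= tau * abs(shift_e2),
                   "normalized", "partial")

  out <- data.frame(
    gene_id = ids[keep],
    direction = dirs[keep],
    mean_control = unname(mc[keep]),
    mean_e2 = unname(me[keep]),
    mean_e2_ici = unname(mi[keep]),
    fold_change_e2 = unname(2^abs(shift_e2[keep])),
    rescue = rescue[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}
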