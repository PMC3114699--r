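#' Significance Analysis of Microarrays (SAM)
#'
#' Tusher-style moderated statistics for two-class and multiclass designs:
#' a per-gene score d = r / (s + s0), where r is the mean-difference
#' numerator (two-class) or the between-class F-like numerator (multiclass),
#' s is the pooled standard error, and s0 is a small "fudge" constant chosen
#' to stabilize the coefficient of variation of d across the spread of s
#' (see [tune_s0()]).  Significance is assessed against a label-permutation
#' null with a delta-slab threshold and median-false-call FDR
#' ([estimate_fdr()]).
#'
#' @param em an [expression_matrix()].
#' @param design `"twoclass"` or `"multiclass"`.
#' @param class_pair for the two-class design, a character pair
#'   `c(treatment, reference)`; d > 0 means higher in `class_pair[1]`.
#'   Ignored for multiclass.
#' @param s0 optional fixed fudge factor; by default tuned by [tune_s0()].
#' @param fold_classes pair `c(treatment, reference)` used for the reported
#'   linear fold change `2^(mean_treat - mean_ref)`; defaults to
#'   `class_pair` (two-class) or `c("E2", "control")` when those labels
#'   exist (multiclass), else the first two class labels.
#' @return an object of class `SamScores`: list with `gene_ids`, `d`
#'   (statistic), `s` (gene scatter), `s0`, `r` (numerator),
#'   `fold_change`, `design`, `classes` (per-sample labels used),
#'   `values` (the gene x sample submatrix the statistic was computed on),
#'   and `q_value` (`NA` until [estimate_fdr()] fills it).
#' @export
compute_scores <- function(em, design = c("multiclass", "twoclass"),
                           class_pair = NULL, s0 = NULL,
                           fold_classes = NULL) {
  design <- match.arg(design)
  if (design == "twoclass") {
    if (is.null(class_pair) || length(class_pair) != 2)
      stop_cls("estrocon_design_error",
               "twoclass design requires class_pair = c(treatment, reference)")
    keep <- em$classes %in% class_pair
    vals <- em$values[, keep, drop = FALSE]
    y <- em$classes[keep]
    labs <- class_pair
  } else {
    vals <- em$values
    y <- em$classes
    labs <- unique(y)
    if (length(labs) < 2)
      stop_cls("estrocon_design_error", "multiclass design needs >= 2 classes")
  }
  cnt <- vapply(labs, function(l) sum(y == l), 1L)
  if (any(cnt < 2))
    stop_cls("estrocon_design_error",
             "every class needs >= 2 samples; got ",
             paste(sprintf("%s=%d", labs, cnt), collapse = ", "))

  st <- sam_statistic(vals, y, labs, s0 = 0)
  if (is.null(s0)) s0 <- tune_s0(st$s, st$r)
  d <- sam_ratio(st$r, st$s + s0)

  fc_pair <- fold_classes %||%
    (if (design == "twoclass") class_pair
     else if (all(c("E2", "control") %in% labs)) c("E2", "control")
     else labs[1:2])
  m_t <- rowMeans(vals[, y == fc_pair[1], drop = FALSE], na.rm = TRUE)
  m_r <- rowMeans(vals[, y == fc_pair[2], drop = FALSE], na.rm = TRUE)
  fold <- 2^(m_t - m_r)

  structure(list(
    gene_ids = rownames(vals), d = unname(d), s = unname(st$s),
    s0 = s0, r = unname(st$r), fold_change = unname(fold),
    design = design, classes = y, class_labels = labs, values = vals,
    q_value = rep(NA_real_, nrow(vals))
  ), class = "SamScores")
}

# Core SAM numerator r and scatter s for a gene x sample matrix under
# labels y (levels labs).  Two labels: r = mean(labs[1]) - mean(labs[2]),
# s = pooled SE.  More: r = sqrt((sum n_k / prod n_k) *
# sum_k n_k (xbar_k - xbar)^2), s = sqrt(sum(1/n_k) * pooled within-class
# variance).  Missing entries are ignored per gene; genes with < 2
# non-missing values in some class get NA.
sam_statistic <- function(vals, y, labs, s0 = 0) {
  K <- length(labs)
  n_k <- matrix(0L, nrow(vals), K)
  m_k <- matrix(NA_real_, nrow(vals), K)
  ss_k <- matrix(NA_real_, nrow(vals), K) # within-class sums of squares
  for (j in seq_len(K)) {
    sub <- vals[, y == labs[j], drop = FALSE]
    nn <- rowSums(!is.na(sub))
    mm <- rowMeans(sub, na.rm = TRUE)
    n_k[, j] <- nn
    m_k[, j] <- mm
    ss_k[, j] <- rowSums((sub - mm)^2, na.rm = TRUE)
  }
  bad <- rowSums(n_k < 2L) > 0
  if (all(bad))
    stop_cls("estrocon_design_error",
             "every gene has a class with < 2 non-missing values")
  n_tot <- rowSums(n_k)
  pooled_var <- rowSums(ss_k) / (n_tot - K)
  inv_n <- rowSums(1 / n_k)
  s <- sqrt(inv_n * pooled_var)
  if (K == 2) {
    r <- m_k[, 1] - m_k[, 2]
  } else {
    gm <- rowSums(n_k * m_k) / n_tot
    between <- rowSums(n_k * (m_k - gm)^2)
    fac <- n_tot / apply(n_k, 1, prod)
    r <- sqrt(fac * between)
  }
  r[bad] <- NA_real_
  s[bad] <- NA_real_
  list(r = r, s = s, d = sam_ratio(r, s + s0))
}

# d = r / denom with the 0/0 case (constant gene, no shrinkage) defined as 0
sam_ratio <- function(r, denom) {
  d <- r / denom
  d[!is.na(r) & r == 0 & denom == 0] <- 0
  d
}

#' Tune the SAM fudge factor s0
#'
#' Evaluates candidate s0 values at the 0, 5, ..., 100 percentiles of the
#' gene scatters s and picks the one minimizing the coefficient of
#' variation of the median absolute deviation of d = r/(s + s0) computed in
#' 100 windows of s.  This flattens the dependence of the spread of d on s,
#' so low-variance genes do not dominate the significant list.
#'
#' @param s numeric vector of per-gene scatters (pooled SEs).
#' @param r numeric vector of per-gene numerators.
#' @return scalar s0 >= 0.
#' @export
tune_s0 <- function(s, r) {
  ok <- is.finite(s) & is.finite(r)
  s <- s[ok]; r <- r[ok]
  if (length(s) < 10) return(0)
  if (stats::sd(s) == 0) {
    warning("constant gene scatter: s0 set to 0")
    return(0)
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- unname(stats::quantile(s, alphas, type = 7))
  n_win <- min(100L, max(5L, floor(length(s) / 20)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0a) {
    d <- r / (s + s0a)
    v <- tapply(d, win, stats::mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, 1.0)
  cand[which.min(cv)]
}

#' Permutation-null FDR estimation and q-values (delta table)
#'
#' Builds the SAM delta table: sample (or exhaustively enumerate, when
#' feasible) assignments of class labels to samples, recompute the d
#' statistic under each, and for a grid of delta thresholds find the
#' asymmetric cutpoints where the sorted observed statistics leave the
#' "slab" of width delta around the permutation-averaged order statistics.
#' FDR at each delta is `pi0 * median false calls / called`, with
#' `pi0 = min(1, 2 * fraction of observed d inside the null interquartile
#' range)`.  A gene's q-value is the minimum FDR over deltas at which it is
#' called, made monotone in |d| rank.
#'
#' @param scores a `SamScores` object from [compute_scores()].
#' @param n_perm number of label permutations (default 100).  When this
#'   meets or exceeds the number of distinct label assignments the null is
#'   enumerated exhaustively instead.
#' @param seed integer seed for the permutation sampler.
#' @param n_delta size of the delta grid.
#' @return the input `scores` with `q_value` filled in, plus elements
#'   `delta_table` (data.frame delta / called / median_false / fdr /
#'   cutlow / cutup), `pi0`, `n_perm_used`, `exhaustive`, `seed`.
#' @export
estimate_fdr <- function(scores, n_perm = 100, seed = 1, n_delta = 60) {
  stopifnot(inherits(scores, "SamScores"))
  if (n_perm < 25)
    warning("n_perm < 25 gives a coarse null; consider more permutations")
  vals <- scores$values
  y <- scores$classes
  labs <- scores$class_labels %||% unique(y)
  signed <- scores$design == "twoclass"

  perms <- make_permutations(y, n_perm, seed)
  d_null <- vapply(seq_len(ncol(perms)), function(j) {
    st <- sam_statistic(vals, perms[, j], labs)
    sam_ratio(st$r, st$s + scores$s0)
  }, numeric(nrow(vals)))

  ok <- is.finite(scores$d)
  d <- scores$d[ok]
  m <- length(d)
  ord <- order(d)
  ds <- d[ord]
  null_mat <- d_null[ok, , drop = FALSE]
  # a permutation can leave a class with < 2 non-missing values for a gene
  # that is fine under the observed labels; such undefined null scores sit
  # at the null centre
  null_mat[!is.finite(null_mat)] <- 0
  null_sorted <- apply(null_mat, 2, sort)
  dbar <- rowMeans(null_sorted)

  qs <- stats::quantile(as.vector(d_null[ok, ]), c(0.25, 0.75), na.rm = TRUE)
  pi0 <- min(1, 2 * mean(d >= qs[1] & d <= qs[2]))

  gap <- abs(ds - dbar)
  # mix rank-based and linear spacing so the calling region is resolved
  # finely both where gaps cluster and in the sparse upper range
  deltas <- sort(unique(c(
    0,
    stats::quantile(gap, probs = seq(0, 1, length.out = n_delta),
                    type = 7, names = FALSE),
    seq(0, max(gap), length.out = n_delta))))

  n_used <- ncol(perms)
  dif <- ds - dbar
  qmin <- rep(Inf, m)
  tab <- data.frame(delta = deltas, called = 0L, median_false = 0,
                    fdr = 0, cutlow = -Inf, cutup = Inf)
  null_vec <- null_mat
  for (i in seq_along(deltas)) {
    del <- deltas[i]
    cutup <- Inf; cutlow <- -Inf
    o1 <- which(dif > del & dbar > 0)
    if (length(o1)) cutup <- ds[min(o1)]
    if (signed) {
      o2 <- which(-dif > del & dbar < 0)
      if (length(o2)) cutlow <- ds[max(o2)]
    }
    called_mask <- d >= cutup | d <= cutlow
    called <- sum(called_mask)
    false_per_perm <- colSums(null_vec >= cutup | null_vec <= cutlow)
    med_false <- stats::median(false_per_perm)
    fdr <- if (called == 0) 0 else min(1, pi0 * med_false / called)
    tab$called[i] <- called
    tab$median_false[i] <- med_false
    tab$fdr[i] <- fdr
    tab$cutlow[i] <- cutlow
    tab$cutup[i] <- cutup
    if (called > 0) qmin[called_mask] <- pmin(qmin[called_mask], fdr)
  }
  q <- ifelse(is.finite(qmin), qmin, 1)
  # enforce monotone nonincreasing q in |d| rank
  o <- order(abs(d), decreasing = TRUE)
  q[o] <- cummax(q[o])

  qfull <- rep(NA_real_, length(scores$d))
  qfull[ok] <- q
  scores$q_value <- qfull
  scores$delta_table <- tab
  scores$pi0 <- unname(pi0)
  scores$n_perm_used <- n_used
  scores$exhaustive <- isTRUE(attr(perms, "exhaustive"))
  scores$seed <- seed
  scores
}

# All distinct assignments of the multiset of labels y to positions, or a
# seeded random sample of n_perm of them.  Columns are label vectors.
make_permutations <- function(y, n_perm, seed) {
  n <- length(y)
  labs <- unique(y)
  cnt <- vapply(labs, function(l) sum(y == l), 1L)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(cnt + 1)))
  if (n_perm >= n_distinct && n_distinct <= 1e5) {
    perms <- enumerate_assignments(labs, cnt, n)
    attr(perms, "exhaustive") <- TRUE
    return(perms)
  }
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample(y), character(n))
  attr(perms, "exhaustive") <- FALSE
  perms
}

# recursively place each label's positions: all distinct multiset perms
enumerate_assignments <- function(labs, cnt, n) {
  res <- list(rep(NA_character_, n))
  for (j in seq_along(labs)) {
    new <- list()
    for (assign in res) {
      free <- which(is.na(assign))
      if (j == length(labs)) {
        assign[free] <- labs[j]
        new[[length(new) + 1]] <- assign
      } else {
        picks <- utils::combn(free, cnt[j], simplify = FALSE)
        for (p in picks) {
          a2 <- assign
          a2[p] <- labs[j]
          new[[length(new) + 1]] <- a2
        }
      }
    }
    res <- new
  }
  do.call(cbind, res)
}

#' Select significant genes at a q-value threshold
#'
#' @param scores a `SamScores` with q-values filled in.
#' @param q_threshold q-value cutoff (genes with `q < q_threshold` are
#'   selected); the study default is 0.08.
#' @return list with character vectors `up` (d > 0), `down` (d < 0), and
#'   `selected` (their union, preserving input order).
#' @export
select_significant <- function(scores, q_threshold = 0.08) {
  if (all(is.na(scores$q_value)))
    stop_cls("estrocon_state_error",
             "q-values not filled in; run estimate_fdr() first")
  sel <- !is.na(scores$q_value) & scores$q_value < q_threshold &
    is.finite(scores$d)
  list(
    up = scores$gene_ids[sel & scores$d > 0],
    down = scores$gene_ids[sel & scores$d < 0],
    selected = scores$gene_ids[sel]
  )
}

#' @export
print.SamScores <- function(x, ...) {
  cat(sprintf("SamScores (%s): %d genes, s0 = %.4g\n",
              x$design, length(x$d), x$s0))
  if (!all(is.na(x$q_value)))
    cat(sprintf("q < 0.08: %d genes (pi0 = %.3f, %d permutations%s)\n",
                sum(x$q_value < 0.08, na.rm = TRUE), x$pi0, x$n_perm_used,
                if (isTRUE(x$exhaustive)) ", exhaustive" else ""))
  invisible(x)
}

#' Write per-gene SAM scores and the delta table as TSV
#'
#' @param scores a `SamScores`.
#' @param path output TSV path for per-gene scores; the delta table goes to
#'   `<path>.delta.tsv` and run metadata to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sam_scores <- function(scores, path) {
  df <- data.frame(gene_id = scores$gene_ids, d = scores$d, s = scores$s,
                   fold_change = scores$fold_change, q = scores$q_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scores$delta_table))
    utils::write.table(scores$delta_table, paste0(path, ".delta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(design = scores$design, s0 = scores$s0,
               n_perm = scores$n_perm_used, seed = scores$seed,
               pi0 = scores$pi0)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
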