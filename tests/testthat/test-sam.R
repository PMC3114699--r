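test_that("two-class d matches the pooled-SE formula and its symmetries", {
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = c(2, 2, 2, 2, 2, 2))
  em <- expression_matrix(vals, rep(c("A", "B"), each = 3))
  sc <- compute_scores(em, "twoclass", class_pair = c("B", "A"), s0 = 0)
  # pooled variance 1, SE sqrt(2/3): d = 3 / sqrt(2/3)
  expect_equal(sc$d[1], 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(sc$d[2], 0)
  expect_equal(sc$fold_change[1], 2^3)

  # permuting sample order within a class changes nothing
  em2 <- expression_matrix(vals[, c(3, 1, 2, 5, 6, 4)],
                           rep(c("A", "B"), each = 3))
  sc2 <- compute_scores(em2, "twoclass", class_pair = c("B", "A"), s0 = 0)
  expect_equal(sc2$d, sc$d)

  expect_error(
    compute_scores(expression_matrix(vals[, 1:4], c("A", "A", "A", "B")),
                   "twoclass", class_pair = c("B", "A")),
    class = "estrocon_design_error")
})

test_that("s0 tuning minimizes the CV criterion found by grid search", {
  set.seed(42)
  m <- 600
  s <- exp(rnorm(m, -1, 0.6))
  # low-scatter genes get inflated raw statistics: shrinkage should engage
  r <- rnorm(m, 0, sqrt(s^2 + 0.15^2))
  s0 <- tune_s0(s, r)
  expect_gt(s0, 0)

  # oracle: independent exhaustive evaluation of the CV-of-window-MAD
  # criterion over the same percentile grid
  cand <- unname(quantile(s, seq(0, 1, by = 0.05), type = 7))
  win <- cut(rank(s, ties.method = "first"),
             breaks = min(100, floor(m / 20)), labels = FALSE)
  cv <- sapply(cand, function(s0a) {
    v <- tapply(r / (s + s0a), win, mad)
    v <- v[is.finite(v) & v > 0]
    sd(v) / mean(v)
  })
  expect_equal(s0, cand[which.min(cv)])

  # gene order irrelevant
  perm <- sample(m)
  expect_equal(tune_s0(s[perm], r[perm]), s0)

  expect_warning(s0c <- tune_s0(rep(2, 100), rnorm(100)), "constant")
  expect_equal(s0c, 0)
})

test_that("q-values are valid, rank-monotone and scale-equivariant", {
  ex <- gen_expression(n_genes = 300, n_planted = 30, seed = 5)
  sc <- compute_scores(ex$matrix, "twoclass",
                       class_pair = c("E2", "control"))
  sc <- estimate_fdr(sc, n_perm = 60, seed = 9)
  q <- sc$q_value
  expect_true(all(q >= 0 & q <= 1, na.rm = TRUE))
  o <- order(abs(sc$d), decreasing = TRUE)
  expect_true(all(diff(q[o]) >= 0))

  # multiplying the matrix by c > 0 leaves q untouched
  em_scaled <- expression_matrix(ex$matrix$values * 3.7,
                                 ex$matrix$classes)
  sc_s <- compute_scores(em_scaled, "twoclass",
                         class_pair = c("E2", "control"))
  sc_s <- estimate_fdr(sc_s, n_perm = 60, seed = 9)
  expect_equal(sc_s$q_value, q, tolerance = 1e-10)
  expect_equal(sc_s$d, sc$d * 1, tolerance = 1e-10) # d itself is scale-free

  # delta-table structure: called counts nonincreasing, fdr in [0, 1]
  dt <- sc$delta_table
  expect_true(all(diff(dt$called) <= 0))
  expect_true(all(dt$fdr >= 0 & dt$fdr <= 1))
  expect_true(all(dt$median_false >= 0))
})

test_that("threshold extremes of select_significant behave as stated", {
  ex <- gen_expression(n_genes = 200, n_planted = 20, seed = 2)
  sc <- estimate_fdr(compute_scores(ex$matrix, "multiclass"),
                     n_perm = 40, seed = 3)
  expect_length(select_significant(sc, 0)$selected, 0)
  expect_equal(sort(select_significant(sc, 1.0001)$selected),
               sort(sc$gene_ids[is.finite(sc$d)]))
  sel <- select_significant(sc, 0.08)
  expect_length(intersect(sel$up, sel$down), 0)

  sc_raw <- compute_scores(ex$matrix, "multiclass")
  expect_error(select_significant(sc_raw, 0.08),
               class = "estrocon_state_error")
})

test_that("missing values are tolerated per gene and degenerate designs refused", {
  vals <- matrix(rnorm(200), 20, 10)
  vals[1, c(1, 2, 5)] <- NA  # still >= 2 per class
  rownames(vals) <- sprintf("g%d", 1:20)
  em <- expression_matrix(vals, rep(c("control", "E2", "E2_ICI"),
                                    c(4, 3, 3)))
  sc <- compute_scores(em, "multiclass")
  expect_true(is.finite(sc$d[1]))

  vals[2, 5:7] <- NA  # E2 class empty for g2 -> NA statistic
  em <- expression_matrix(vals, em$classes)
  sc <- compute_scores(em, "multiclass")
  expect_true(is.na(sc$d[2]))
})
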