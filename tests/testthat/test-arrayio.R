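test_that("spot tables read with net intensities and missingness rules", {
  p <- write_spot_fixture(spot_df(3))
  st <- read_spot_table(p)
  expect_s3_class(st, "SpotTable")
  expect_equal(nrow(st), 3)
  expect_false(any(st$missing))
  expect_equal(st$net_cy5, rep(400, 3))

  # background exceeding foreground in Cy3 forces a missing spot
  df <- spot_df(3)
  df$B532[2] <- 900
  st <- read_spot_table(write_spot_fixture(df))
  expect_equal(st$missing, c(FALSE, TRUE, FALSE))

  # nonpositive flag forces missing even with good intensities
  df <- spot_df(2)
  df$Flags[1] <- -50L
  st <- read_spot_table(write_spot_fixture(df))
  expect_equal(st$missing, c(TRUE, FALSE))
})

test_that("format and empty-input errors name the problem", {
  df <- spot_df(3)
  df$Flags <- NULL
  expect_error(read_spot_table(write_spot_fixture(df)),
               class = "estrocon_format_error")
  expect_error(read_spot_table(write_spot_fixture(df)), "Flags")

  empty <- spot_df(0)
  expect_error(read_spot_table(write_spot_fixture(empty)),
               class = "estrocon_empty_input")
})

test_that("lowess normalization removes intensity-dependent bias", {
  # equal channels -> all ratios exactly 0
  st <- read_spot_table(write_spot_fixture(
    spot_df(60, f5 = 300 + 1:60, b5 = 100, f3 = 300 + 1:60, b3 = 100)))
  expect_equal(lowess_normalize(st), rep(0, 60))

  # planted bias M = 0.5*A + noise is flattened: per-A-decile medians ~ 0
  set.seed(11)
  n <- 800
  A <- runif(n, 8, 14)
  M <- 0.5 * A + rnorm(n, 0, 0.1)
  st <- data.frame(spot_id = as.character(1:n), gene_id = "",
                   net_cy5 = 2^(A + M / 2), net_cy3 = 2^(A - M / 2),
                   flag = 100L, missing = FALSE)
  class(st) <- c("SpotTable", "data.frame")
  out <- lowess_normalize(st)
  med <- tapply(out, cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE),
                median)
  expect_true(all(abs(med) < 0.05))

  # length preserved, missing set unchanged
  st$missing[c(3, 7)] <- TRUE
  out <- lowess_normalize(st)
  expect_length(out, n)
  expect_identical(which(is.na(out)), c(3L, 7L))

  # idempotent on bias-free data: renormalizing changes nothing measurable
  st0 <- read_spot_table(write_spot_fixture(
    spot_df(50, f5 = 200 * (1:50) + 100, b5 = 100,
            f3 = 100 * (1:50) + 100, b3 = 100)))
  r1 <- lowess_normalize(st0)
  A0 <- 0.5 * log2(st0$net_cy5 * st0$net_cy3)
  st1 <- st0
  st1$net_cy5 <- 2^(A0 + r1 / 2)
  st1$net_cy3 <- 2^(A0 - r1 / 2)
  expect_lt(max(abs(lowess_normalize(st1) - r1)), 1e-6)

  expect_error(lowess_normalize(read_spot_table(write_spot_fixture(
    spot_df(5)))[1:5, ][rep(1, 3), ]), class = "estrocon_insufficient_data")
})

test_that("matrix assembly applies the missingness cap at the boundary", {
  n_probe <- 8
  mk <- function(miss_probe1) {
    lapply(1:10, function(j) {
      v <- rep(j / 10, n_probe)
      if (j <= miss_probe1) v[1] <- NA
      v
    })
  }
  classes <- rep(c("control", "E2", "E2_ICI"), c(4, 3, 3))
  ids <- sprintf("p%d", 1:n_probe)

  em7 <- build_matrix(mk(7), classes, ids)          # 7 missing -> dropped
  expect_false("p1" %in% rownames(em7$values))
  expect_equal(attr(em7, "n_dropped"), 1L)

  em6 <- build_matrix(mk(6), classes, ids)          # exactly 6 -> retained
  expect_true("p1" %in% rownames(em6$values))

  em0 <- build_matrix(mk(0), classes, ids)
  expect_equal(nrow(em0$values), n_probe)

  # never invents values: every non-missing entry equals an input ratio
  expect_equal(em6$values["p3", 4], mk(6)[[4]][3])

  # retained count monotone nonincreasing as the cap tightens
  kept <- vapply(6:0, function(cap)
    nrow(build_matrix(mk(6), classes, ids, max_missing = cap)$values), 1L)
  expect_true(all(diff(kept) <= 0))

  expect_error(build_matrix(c(mk(0), list(1:3)), c(classes, "E2"),
                            ids), class = "estrocon_alignment_error")
})
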