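test_that("Buhmann equivalization follows income / size^theta", {
  expect_equal(equivalize_income(20000, 4, 0.5), 10000)
  expect_equal(equivalize_income(20000, 1, 0.5), 20000)
  expect_equal(equivalize_income(9000, 3, 1.0), 3000)
  expect_equal(equivalize_income(5000, 3, 0), 5000) # theta = 0 ignores size
  # monotone in income at fixed household size
  inc <- sort(runif(50, 0, 1e5))
  expect_true(all(diff(equivalize_income(inc, 3)) >= 0))
  expect_error(equivalize_income(1000, 0), class = "hinequity_invalid_parameter")
  expect_error(equivalize_income(1000, 2, 1.5), class = "hinequity_invalid_parameter")
  expect_error(equivalize_income(-5, 2), class = "hinequity_invalid_parameter")
})

test_that("weighted fractional ranks match the cumulative-weight construction", {
  expect_equal(weighted_frac_rank(c(10, 20, 30), c(1, 1, 2)), c(0.125, 0.375, 0.75))
  expect_equal(weighted_frac_rank(c(1000, 2000, 3000, 4000)), (2 * (1:4) - 1) / 8)
  expect_equal(weighted_frac_rank(c(5, 5), c(1, 1)), c(0.5, 0.5))
  # ranks follow income order, not input order
  expect_equal(weighted_frac_rank(c(30, 10, 20), c(2, 1, 1)), c(0.75, 0.125, 0.375))
  expect_error(weighted_frac_rank(numeric(0)), class = "hinequity_invalid_input")
  expect_error(weighted_frac_rank(c(1, 2), c(1, 0)), class = "hinequity_invalid_input")
  expect_error(weighted_frac_rank(c(1, 2), c(1, -1)), class = "hinequity_invalid_input")
})

test_that("rank properties: mean 1/2, monotone invariance, weight replication, tie order-invariance", {
  set.seed(71)
  for (trial in 1:20) {
    n <- sample(2:60, 1)
    inc <- round(rlnorm(n, 9, 1), sample(c(-2, 0, 3), 1)) # induces ties
    w <- rgamma(n, 2, 1) + 0.1
    r <- weighted_frac_rank(inc, w)
    expect_lt(abs(weighted.mean(r, w) - 0.5), 1e-12)
    expect_true(all(r > 0 & r < 1))
    # invariant under strictly increasing transforms of income
    expect_equal(weighted_frac_rank(log1p(inc), w), r)
    expect_equal(weighted_frac_rank(rank(inc, ties.method = "min"), w), r)
    # duplicating a row with halved weight leaves all other ranks unchanged
    i <- sample(n, 1)
    inc2 <- c(inc, inc[i])
    w2 <- c(w, w[i] / 2)
    w2[i] <- w[i] / 2
    r2 <- weighted_frac_rank(inc2, w2)
    expect_lt(max(abs(r2[seq_len(n)][-i] - r[-i])), 1e-12)
    # order invariance
    p <- sample(n)
    expect_equal(weighted_frac_rank(inc[p], w[p]), r[p])
  }
})

test_that("add_income_ranks ranks within groups and appends derived columns", {
  d <- tiny_dataset(n = 300, groups = c("A", "B"))
  d2 <- add_income_ranks(dplyr::select(d, -eq_income, -log_eq_income, -frac_rank))
  expect_true(all(c("eq_income", "log_eq_income", "frac_rank") %in% names(d2)))
  expect_equal(d2$eq_income, d2$income_hh / sqrt(d2$hh_size))
  for (g in c("A", "B")) {
    sub <- d2[d2$group == g, ]
    expect_lt(abs(weighted.mean(sub$frac_rank, sub$weight) - 0.5), 1e-12)
  }
})

test_that("validation drops invalid rows and flags undersized groups", {
  d <- tiny_dataset(n = 150)
  v <- validate_dataset(d)
  expect_equal(v$n_dropped, 0)
  expect_equal(sum(v$report$n_invalid), 0)
  expect_length(v$unestimable, 0)

  d_bad <- d
  d_bad$y_postponed[3] <- 2
  d_bad$weight[5] <- -1
  d_bad$chronic[9] <- NA
  v2 <- suppressMessages(validate_dataset(d_bad))
  expect_equal(v2$n_dropped, 3)
  expect_equal(nrow(v2$data), nrow(d) - 3)
  rep2 <- v2$report
  expect_equal(rep2$n_invalid[rep2$column == "y_postponed"], 1)
  expect_equal(rep2$n_invalid[rep2$column == "weight"], 1)
  expect_equal(rep2$n_missing[rep2$column == "chronic"], 1)

  # a 10-row group cannot identify a ~20-column model: flagged, not an error
  d_small <- dplyr::bind_rows(d, dplyr::mutate(tiny_dataset(n = 10, seed = 9), group = "tiny"))
  expect_warning(v3 <- validate_dataset(d_small), "unestimable")
  expect_equal(v3$unestimable, "tiny")
})

test_that("survey extracts round-trip through CSV with column mapping", {
  d <- tiny_dataset(n = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::rename(d, land = group), path)
  d2 <- read_survey_extract(path, col_map = c(group = "land"))
  expect_equal(d2$group, d$group)
  expect_s3_class(d2$sah, "factor")
  expect_equal(levels(d2$age_group)[1], "50-64")
  expect_equal(as.character(d2$sah), as.character(d$sah))
})
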