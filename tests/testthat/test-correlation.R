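test_that("pearson_r matches a direct covariance oracle and exact cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # reconstructed day-1 effective-surface doses vs asbestos-normalized PMN
  r <- pearson_r(c(0.96, 2.52, 5.52) * 1e-3, c(1, 2.8, 5.7))
  expect_equal(r, 0.9989408, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("pearson_r is affine-invariant and antisymmetric under negation", {
  set.seed(12)
  for (i in 1:10) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    r <- pearson_r(x, y)
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(x, a * y + b), r, tolerance = 1e-12)
    expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs fail loudly rather than NaN", {
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "esadose_domain_error")
  expect_error(pearson_r(c(1, 2, 3), c(5, 5, 5)),
               class = "esadose_domain_error")
  expect_error(pearson_r(1:3, 1:4), class = "esadose_validation_error")
  expect_error(pearson_r(1:2, 1:2), class = "esadose_validation_error")
  expect_error(correlation_p(1.2, 1), class = "esadose_domain_error")
})

test_that("df = 1 reference reproduces the published significance split", {
  # t with 1 df is standard Cauchy: p = 1 - (2/pi) atan(|t|)
  p997 <- correlation_p(0.997, 1)
  t997 <- 0.997 * sqrt(1 / (1 - 0.997^2))
  expect_equal(p997, 1 - (2 / pi) * atan(t997), tolerance = 1e-12)
  expect_equal(p997, 0.0493, tolerance = 1e-2)
  expect_lt(p997, 0.05)
  p995 <- correlation_p(0.995, 1)
  expect_equal(p995, 0.0637, tolerance = 1e-2)
  expect_gt(p995, 0.05)
  expect_equal(correlation_p(0, 1), 1)
  expect_equal(correlation_p(1, 1), 0)
  expect_equal(correlation_p(-1, 5), 0)
  # the boundary itself
  rc <- critical_r(0.05, 1)
  expect_equal(rc, 12.7062047 / sqrt(1 + 12.7062047^2), tolerance = 1e-7)
  expect_equal(rc, 0.99692, tolerance = 1e-5)
  expect_gt(correlation_p(rc - 1e-6, 1), 0.05)
  expect_lt(correlation_p(rc + 1e-6, 1), 0.05)
  # p monotone decreasing in |r| at fixed df
  for (df in c(1L, 3L, 10L)) {
    ps <- vapply(seq(0, 0.999, by = 0.037), correlation_p, numeric(1), df = df)
    expect_true(all(diff(ps) < 0))
  }
})

test_that("fixture fit flags day-1 PMN and protein under ESA, nothing under BET", {
  fit <- correlate_dose_metrics(
    fixture_outcomes(), fixture_dose_table(), metrics = c("ssa", "esa"),
    outcomes = c("PMN", "protein", "4HNE"), timepoints = 1,
    reference = "asbestos", df = 1)
  res <- fit$results
  sig_esa <- res[res$metric == "esa" & res$significant, "outcome"]
  expect_setequal(sig_esa, c("PMN", "protein"))
  expect_false(any(res$significant[res$metric == "ssa"]))
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$df == 1))
  expect_identical(res$significant, res$p < fit$alpha)
  # deterministic ordering: metric, then outcome, then timepoint
  expect_identical(res, res[order(res$metric, res$outcome, res$timepoint_day), ],
                   ignore_attr = "row.names")
  # r for day-1 PMN under the effective-surface metric is ~0.997-0.999
  r_pmn <- res$r[res$metric == "esa" & res$outcome == "PMN"]
  expect_equal(r_pmn, 0.997, tolerance = 0.01)
})

test_that("metric report pairs metrics per outcome and flags the winner", {
  fit <- correlate_dose_metrics(
    fixture_outcomes(), fixture_dose_table(), metrics = c("ssa", "esa"),
    outcomes = c("PMN", "protein", "4HNE"), timepoints = 1,
    reference = "asbestos", df = 1)
  rep <- metric_report(fit)
  expect_equal(nrow(rep), 3)
  expect_true(all(c("r_ssa", "r_esa", "p_ssa", "p_esa", "winner") %in% names(rep)))
  expect_true(all(rep$winner == "esa"))
  expect_gt(sum(rep$sig_esa), sum(rep$sig_ssa))
  # summary counts agree
  s <- summary(fit)
  expect_equal(unname(s$significant_per_metric["esa"]), 2L)
  expect_equal(unname(s$significant_per_metric["ssa"]), 0L)
  # empty fit gives an empty report without error
  empty <- correlate_dose_metrics(
    fixture_outcomes(), fixture_dose_table(), metrics = "esa",
    timepoints = 99, reference = "asbestos")
  expect_identical(nrow(metric_report(empty)), 0L)
})

test_that("noise-free synthetic panels correlate perfectly on the generating metric", {
  doses <- synthetic_dose_table(6)
  panel <- simulate_outcome_panel(doses, metric = "esa", sigma = 0, seed = 3)
  fit <- correlate_dose_metrics(panel, doses, metrics = c("esa", "ssa"),
                                normalization = "control-fold")
  res <- fit$results
  expect_equal(res$r[res$metric == "esa"], 1, tolerance = 1e-9)
  expect_true(all(res$significant[res$metric == "esa"]))
  # the competing, non-collinear metric cannot reach |r| = 1
  expect_lt(abs(res$r[res$metric == "ssa"]), 1 - 1e-6)
})

test_that("coverage gaps raise an explicit missing-data error", {
  panel <- fixture_outcomes()
  doses <- fixture_dose_table()
  # LDH is only observed for CNF
  expect_error(
    correlate_dose_metrics(panel, doses, outcomes = "LDH",
                           reference = "asbestos"),
    "missing", class = "esadose_missing_data_error")
  # unnamed mode silently restricts itself to fully covered cells
  fit <- correlate_dose_metrics(panel, doses, reference = "asbestos")
  expect_false("LDH" %in% fit$results$outcome)
  expect_error(
    correlate_dose_metrics(panel, doses, outcomes = "PMN"),
    class = "esadose_validation_error") # reference normalization needs a reference
  expect_error(
    correlate_dose_metrics(panel, doses, outcomes = "nope",
                           reference = "asbestos"),
    class = "esadose_lookup_error")
})
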