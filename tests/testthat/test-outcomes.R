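test_that("fold change is the ratio to a positive control baseline", {
  # printed day-1 control neutrophil baseline x printed 700-fold influx
  expect_equal(fold_change(1106e3, 1.58e3), 700)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(c(2, 4), c(2, 2)), c(1, 2))
  expect_error(fold_change(5, 0), class = "esadose_domain_error")
  expect_error(fold_change(5, -1), class = "esadose_domain_error")
})

test_that("reference normalization cancels scale", {
  obs <- data.frame(material_id = c("a", "b", "c"), outcome = "PMN",
                    timepoint_day = 1, value = c(1, 2.8, 5.7))
  panel <- outcome_panel(obs)
  rel <- relative_to_reference(panel, "PMN", 1, "a")
  expect_equal(unname(rel[c("a", "b", "c")]), c(1, 2.8, 5.7))
  # multiplying every raw value by a constant changes nothing
  obs2 <- obs; obs2$value <- obs$value * 37.2
  rel2 <- relative_to_reference(outcome_panel(obs2), "PMN", 1, "a")
  expect_equal(rel2, rel)
  # single-material panel normalized to itself
  solo <- outcome_panel(obs[1, , drop = FALSE])
  expect_equal(unname(relative_to_reference(solo, "PMN", 1, "a")), 1)
  expect_error(relative_to_reference(panel, "PMN", 1, "zz"),
               class = "esadose_lookup_error")
  obs0 <- obs; obs0$value[1] <- 0
  expect_error(relative_to_reference(outcome_panel(obs0), "PMN", 1, "a"),
               class = "esadose_domain_error")
})

test_that("stereology estimators compose to the wall-thickness formula", {
  est <- stereology_estimates(50, 200, 30, 1200)
  expect_equal(est$vv, 0.25)
  expect_equal(est$sv, 0.05)
  expect_equal(alveolar_wall_thickness(est$vv, est$sv), 10)
  expect_equal(alveolar_wall_thickness(0, 0.05), 0)
  expect_equal(alveolar_wall_thickness(0.5, 1), 1)
  expect_equal(stereology_estimates(0, 100, 0, 50)$vv, 0)
  expect_equal(stereology_estimates(100, 100, 3, 50)$vv, 1)
  # composed closed form: 2 (P/PT) / (2 I / L) = P L / (PT I)
  set.seed(42)
  for (i in 1:20) {
    pt <- sample(50:500, 1); p <- sample.int(pt, 1)
    ii <- sample(1:200, 1); l <- stats::runif(1, 100, 5000)
    est <- stereology_estimates(p, pt, ii, l)
    expect_equal(alveolar_wall_thickness(est$vv, est$sv),
                 p * l / (pt * ii))
  }
  expect_error(alveolar_wall_thickness(1.2, 0.05),
               class = "esadose_domain_error")
  expect_error(alveolar_wall_thickness(0.5, 0),
               class = "esadose_domain_error")
  expect_error(stereology_estimates(300, 200, 30, 1200),
               class = "esadose_domain_error")
})

test_that("outcome tables round-trip bit-for-bit and reject duplicates", {
  set.seed(7)
  obs <- expand.grid(material_id = c("a", "b", "c"),
                     outcome = c("PMN", "protein"),
                     timepoint_day = c(1, 7, 28),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs$value <- stats::rlnorm(nrow(obs))
  obs$control_mean <- stats::runif(nrow(obs), 0.1, 2)
  panel <- outcome_panel(obs)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_outcomes(panel, path)
  back <- read_outcomes(path)
  expect_identical(back$value, panel$value)
  expect_identical(back$control_mean, panel$control_mean)
  expect_identical(back$material_id, panel$material_id)
  # duplicate keys are a parse error with row numbers
  dup <- rbind(obs, obs[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_outcomes(path), "rows", class = "esadose_parse_error")
  # empty file with header loads to an empty panel
  utils::write.csv(obs[0, ], path, row.names = FALSE)
  expect_identical(nrow(read_outcomes(path)), 0L)
})

test_that("panel validation guards values, timepoints and keys", {
  base <- data.frame(material_id = "a", outcome = "PMN",
                     timepoint_day = 1, value = 2)
  expect_s3_class(outcome_panel(base), "outcome_panel")
  bad <- base; bad$value <- NaN
  expect_error(outcome_panel(bad), class = "esadose_validation_error")
  bad <- base; bad$timepoint_day <- -1
  expect_error(outcome_panel(bad), class = "esadose_validation_error")
  expect_error(outcome_panel(rbind(base, base)),
               "duplicate", class = "esadose_validation_error")
  expect_error(outcome_panel(base[, -4]), class = "esadose_validation_error")
})

test_that("packaged outcome fixture has the documented structure", {
  panel <- fixture_outcomes()
  expect_setequal(unique(panel$material_id), c("SWCNT", "CNF", "asbestos"))
  expect_setequal(unique(panel$timepoint_day), c(1, 7, 28))
  pmn <- relative_to_reference(panel, "PMN", 1, "asbestos")
  expect_equal(unname(pmn[c("asbestos", "CNF", "SWCNT")]), c(1, 2.8, 5.7))
  # reconstructed cells are flagged as such
  expect_true(all(c("printed", "reconstructed") %in% panel$provenance))
  rec <- panel[panel$provenance == "reconstructed", ]
  expect_true(all(rec$material_id == "asbestos"))
})
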