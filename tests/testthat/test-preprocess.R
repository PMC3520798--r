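test_that("greedy matching finds the minimal-distance pairing", {
  p <- toy_panel(values = list(a1 = rep(1, 4)),
                 sex = c("M", "M", "F", "F"),
                 covs = tibble::tibble(age = c(30, 40, 39, 31)))
  res <- match_sexes(p, "age")
  # brute force over the two possible pairings: (30,31)+(40,39) wins
  got <- res$pairs %>% dplyr::arrange(male_id)
  ages <- p$samples$age[match(c(got$male_id, got$female_id),
                              p$samples$sample_id)]
  expect_equal(ages, c(30, 40, 31, 39))
  expect_equal(res$report$n_pairs, 2L)
  expect_equal(res$report$n_discarded, 0L)
})

test_that("unbalanced cohorts are trimmed and reported", {
  p <- toy_panel(values = list(a1 = rep(1, 5)),
                 sex = c("M", "M", "M", "F", "F"),
                 covs = tibble::tibble(age = c(30, 35, 50, 31, 36)))
  res <- match_sexes(p, "age")
  expect_equal(res$report$n_pairs, 2L)
  expect_equal(res$report$n_discarded, 1L)
  expect_equal(nrow(res$panel$samples), 4)
  expect_equal(sum(res$panel$samples$sex == "M"),
               sum(res$panel$samples$sex == "F"))
})

test_that("a cohort lacking one sex is dropped with a warning", {
  p <- toy_panel(values = list(a1 = rep(1, 3)), sex = c("M", "M", "M"))
  expect_warning(res <- match_sexes(p), "lacks one sex")
  expect_equal(nrow(res$panel$samples), 0)
})

test_that("matching with identical covariates keeps a balanced cohort intact", {
  p <- toy_panel(values = list(a1 = rep(1, 4)),
                 sex = c("M", "F", "M", "F"),
                 covs = tibble::tibble(age = rep(30, 4)))
  res <- match_sexes(p, "age")
  expect_equal(nrow(res$panel$samples), 4)
  # idempotent: re-matching changes nothing
  res2 <- match_sexes(res$panel, "age")
  expect_equal(dplyr::arrange(res2$panel$samples, sample_id),
               dplyr::arrange(res$panel$samples, sample_id))
})

test_that("out-of-range cells become half-min / double-max", {
  p <- toy_panel(
    values = list(a1 = c(2, 4, 8, NA, NA), a2 = c(1, 2, 3, 4, 5)),
    sex = c("M", "M", "F", "F", "M"),
    status = list(a1 = c("OK", "OK", "OK", "BELOW_RANGE", "ABOVE_RANGE"))
  )
  res <- replace_out_of_range(p)
  m <- res$panel$measurements
  expect_equal(m$value[m$sample_id == "s04" & m$analyte == "a1"], 1.0)
  expect_equal(m$value[m$sample_id == "s05" & m$analyte == "a1"], 16.0)
  expect_true(all(m$status[m$analyte == "a1"] == "OK"))
  # untouched analyte is the identity
  expect_equal(m$value[m$analyte == "a2"],
               p$measurements$value[p$measurements$analyte == "a2"])
  rep_a1 <- res$report[res$report$analyte == "a1", ]
  expect_equal(rep_a1$n_low, 1)
  expect_equal(rep_a1$n_high, 1)
  # idempotent
  res2 <- replace_out_of_range(res$panel)
  expect_identical(res2$panel$measurements$value,
                   res$panel$measurements$value)
})

test_that("an analyte that is entirely out of range is flagged, not replaced", {
  p <- toy_panel(values = list(a1 = c(NA, NA), a2 = c(1, 2)),
                 sex = c("M", "F"),
                 status = list(a1 = c("BELOW_RANGE", "BELOW_RANGE")))
  res <- replace_out_of_range(p)
  expect_true(res$report$unreplaceable[res$report$analyte == "a1"])
  m <- res$panel$measurements
  expect_true(all(m$status[m$analyte == "a1"] == "BELOW_RANGE"))
})

test_that("the 70% missingness rule uses a strict inequality", {
  v8 <- c(1, 2, rep(NA, 8))           # 0.8 missing -> dropped
  v7 <- c(1, 2, 3, rep(NA, 7))        # 0.7 missing -> kept
  p <- toy_panel(values = list(a8 = v8, a7 = v7, full = 1:10),
                 sex = rep(c("M", "F"), 5))
  res <- filter_missing_analytes(p, 0.70)
  kept <- unique(res$panel$measurements$analyte)
  expect_setequal(kept, c("a7", "full"))
  expect_true(res$report$dropped[res$report$analyte == "a8"])
  expect_equal(res$report$missing_fraction[res$report$analyte == "a7"], 0.7)
  # no analyte above threshold: identity
  res2 <- filter_missing_analytes(res$panel, 0.70)
  expect_identical(res2$panel$measurements, res$panel$measurements)
})

test_that("the 4-SD outlier rule is a single pooled pass", {
  p <- toy_panel(values = list(a1 = c(rep(10, 99), 1000),
                               flat = rep(5, 100)),
                 sex = rep(c("M", "F"), 50))
  res <- remove_outliers(p, 4)
  m <- res$panel$measurements
  expect_equal(sum(m$status == "OUTLIER_REMOVED"), 1)
  expect_equal(m$status[m$analyte == "a1" & m$sample_id == "s100"],
               "OUTLIER_REMOVED")
  # zero-SD analyte untouched
  expect_true(all(m$status[m$analyte == "flat"] == "OK"))
  expect_equal(res$report$n_outliers_removed[res$report$analyte == "a1"], 1)
  # single pass: after removal the remaining values are all equal, and a
  # second application removes nothing
  res2 <- remove_outliers(res$panel, 4)
  expect_equal(sum(res2$panel$measurements$status == "OUTLIER_REMOVED"), 1)
})

test_that("values within the threshold are never removed", {
  set.seed(1)
  v <- qnorm(seq(0.01, 0.99, length.out = 50))  # max |z| ~ 2.4
  p <- toy_panel(values = list(a1 = v), sex = rep(c("M", "F"), 25))
  res <- remove_outliers(p, 4)
  expect_equal(sum(res$panel$measurements$status == "OUTLIER_REMOVED"), 0)
})

test_that("replacement precedes outlier removal in the pipeline", {
  # an ABOVE_RANGE cell replaced by 2*max lands > 4 SD from the mean, so
  # with the documented order it must end as OUTLIER_REMOVED
  vals <- c(seq(9.8, 10.5, length.out = 19), NA)
  p <- toy_panel(values = list(a1 = vals, pad = (1:20) * 1.0),
                 sex = rep(c("M", "F"), 10),
                 status = list(a1 = c(rep("OK", 19), "ABOVE_RANGE")))
  res <- preprocess_panel(p, run_config())
  m <- res$panel$measurements
  expect_equal(m$status[m$analyte == "a1" & m$sample_id == "s20"],
               "OUTLIER_REMOVED")
  # had outlier removal run first, the cell would have stayed censored
  alt <- remove_outliers(p, 4)
  expect_equal(alt$panel$measurements$status[
    alt$panel$measurements$analyte == "a1" &
      alt$panel$measurements$sample_id == "s20"], "ABOVE_RANGE")
})

test_that("every input cell is accounted for after preprocessing", {
  d <- default_design(scale = 0.2, seed = 13)
  s <- simulate_study(d)
  res <- preprocess_panel(s$panel, run_config())
  n_in_samples <- nrow(s$panel$samples)
  n_kept_samples <- nrow(res$panel$samples)
  n_kept_analytes <- length(panel_analytes(res$panel))
  # retained measurements table is exactly samples x analytes
  expect_equal(nrow(res$panel$measurements),
               n_kept_samples * n_kept_analytes)
  # all statuses legal and values consistent
  m <- res$panel$measurements
  expect_true(all(m$status %in% c("OK", "MISSING", "OUTLIER_REMOVED",
                                  "BELOW_RANGE", "ABOVE_RANGE")))
  expect_true(all(!is.na(m$value[m$status == "OK"])))
  # report totals reconcile with the matching stage
  expect_equal(sum(res$report$matching$n_pairs) * 2 +
                 sum(res$report$matching$n_discarded), n_in_samples)
})
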