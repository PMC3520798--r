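test_that("homogeneous effects collapse to the fixed-effect mean", {
  res <- pool_random_effects(rep(0.3, 3), rep(0.01, 3))
  expect_equal(res$delta_pooled, 0.3)
  expect_equal(res$Q, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$variance_pooled, 0.01 / 3)
  expect_equal(res$p_het, 1)
})

test_that("DerSimonian-Laird arithmetic matches the hand-derived example", {
  # delta = {0.1, 0.3, 0.8}, v = {0.04, 0.01, 0.01}:
  # w = {25, 100, 100}; delta_FE = 0.5; Q = 4 + 4 + 9 = 17;
  # C = 225 - 20625/225; tau2 = 15/C = 0.1125;
  # w* = {6.557377, 8.163265, 8.163265} -> delta* = 0.4210526
  res <- pool_random_effects(c(0.1, 0.3, 0.8), c(0.04, 0.01, 0.01))
  expect_equal(res$Q, 17)
  expect_equal(res$tau2, 0.1125)
  expect_equal(res$delta_pooled, 0.4210526316, tolerance = 1e-9)
  expect_equal(sqrt(res$variance_pooled), 0.2090426521, tolerance = 1e-9)
  expect_equal(res$p, 0.04398908, tolerance = 1e-6)
  expect_equal(res$ci_low, 0.0113365622, tolerance = 1e-8)
  expect_equal(res$ci_high, 0.8307687010, tolerance = 1e-8)
})

test_that("pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(41)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    d <- runif(k, -0.9, 0.9)
    v <- runif(k, 0.002, 0.08)
    ours <- pool_random_effects(d, v)
    ref <- metafor::rma(yi = d, vi = v, method = "DL")
    expect_equal(ours$delta_pooled, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
    expect_equal(sqrt(ours$variance_pooled), ref$se, tolerance = 1e-10)
  }
})

test_that("fewer than three cohorts is excluded, not an error", {
  res <- pool_random_effects(c(0, 0.6), c(0.01, 0.01))
  expect_true(res$excluded)
  expect_true(is.na(res$delta_pooled))
  expect_error(pool_random_effects(c(0, 0.1, 0.2), c(0.01, 0, 0.01)),
               "> 0")
})

test_that("heterogeneity p-values come from the chi-squared tail", {
  expect_equal(heterogeneity_test(0, 5), 1)
  expect_equal(heterogeneity_test(16.92, 10), 0.050, tolerance = 1e-3)
  expect_lt(abs(heterogeneity_test(39, 40) - 0.5), 0.05)  # chi^2 mean = df
  expect_error(heterogeneity_test(1, 1), ">= 2")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(51)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-14)
    # permutation invariance
    ord <- sample(seq_along(p))
    expect_equal(bh_adjust(p[ord]), q[ord], tolerance = 1e-14)
  }
})

test_that("run_meta pools per analyte and reports exclusions", {
  eff <- dplyr::bind_rows(
    tibble::tibble(analyte = "a", cohort_id = paste0("c", 1:4),
                   n_male = 10, n_female = 10,
                   delta = c(0.5, 0.55, 0.45, 0.5), variance = 0.02),
    tibble::tibble(analyte = "b", cohort_id = paste0("c", 1:2),
                   n_male = 10, n_female = 10,
                   delta = c(0, 0.1), variance = 0.02)
  )
  res <- run_meta(eff, alpha = 0.05)
  expect_equal(nrow(res), 2)
  a <- res[res$analyte == "a", ]
  b <- res[res$analyte == "b", ]
  expect_false(a$excluded)
  expect_true(b$excluded)
  expect_equal(a$direction, "male_higher")
  expect_true(a$delta_pooled >= 0.45 && a$delta_pooled <= 0.55)
  expect_error(run_meta(eff[0, ]), "empty")
})

test_that("pooled estimates respect convexity and permutation invariance", {
  set.seed(61)
  for (i in 1:30) {
    k <- sample(3:9, 1)
    d <- runif(k, -0.9, 0.9)
    v <- runif(k, 0.005, 0.05)
    res <- pool_random_effects(d, v)
    expect_gte(res$delta_pooled, min(d))
    expect_lte(res$delta_pooled, max(d))
    ord <- sample(k)
    res2 <- pool_random_effects(d[ord], v[ord])
    expect_equal(res2$delta_pooled, res$delta_pooled, tolerance = 1e-12)
    expect_equal(res2$tau2, res$tau2, tolerance = 1e-12)
  }
})

test_that("zero tau2 reduces to the inverse-variance fixed effect", {
  d <- c(0.2, 0.21, 0.19, 0.2)
  v <- c(0.05, 0.04, 0.05, 0.06)
  res <- pool_random_effects(d, v)
  expect_equal(res$tau2, 0)
  w <- 1 / v
  expect_equal(res$delta_pooled, sum(w * d) / sum(w), tolerance = 1e-12)
  expect_equal(res$variance_pooled, 1 / sum(w), tolerance = 1e-12)
})
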