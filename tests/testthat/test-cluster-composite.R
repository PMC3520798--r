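test_that("pre-clustering outlier replacement is seeded and bounded", {
  m <- matrix(rnorm(200), 4, 50)
  m[2, 1] <- 100  # way past 4 SD
  r1 <- replace_outlying_for_clustering(m, seed = 3)
  r2 <- replace_outlying_for_clustering(m, seed = 3)
  expect_identical(r1, r2)
  expect_true(r1[2, 1] >= min(m[2, -1]) && r1[2, 1] <= max(m[2, -1]))
  r3 <- replace_outlying_for_clustering(m, seed = 4)
  expect_false(r3[2, 1] == r1[2, 1])
  # no outliers: identity
  clean <- matrix(rnorm(200), 4, 50)
  expect_identical(replace_outlying_for_clustering(clean, seed = 1), clean)
})

test_that("k-means on planted clusters recovers the partition", {
  d <- default_design(n_analytes = 60, k_true = 3, lambda = 0.6,
                      frac_nonnull = 0, interaction_cluster = 0,
                      seed = 17)
  s <- simulate_study(d)
  model <- cluster_analytes(s$panel, k = 3, seed = 17, n_restarts = 20)
  j <- dplyr::left_join(model$assignment, s$truth$analytes, by = "analyte")
  expect_gte(ari(j$cluster.x, j$cluster.y), 0.9)
  # reference cohort is the largest (cohort_7)
  expect_equal(model$reference_cohort, "cohort_7")
  # assignments depend only on the reference cohort
  keep <- s$panel$samples$cohort_id %in% c("cohort_7", "cohort_1")
  sub <- analyte_panel(
    s$panel$samples[keep, ],
    s$panel$measurements[s$panel$measurements$sample_id %in%
                           s$panel$samples$sample_id[keep], ])
  model2 <- cluster_analytes(sub, k = 3, seed = 17, n_restarts = 20)
  expect_identical(model2$assignment, model$assignment)
})

test_that("degenerate clusterings behave by contract", {
  p <- toy_panel(values = list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5),
                               b_dup = c(2, 3, 4, 5), c = c(9, 1, 7, 2)),
                 sex = c("M", "F", "M", "F"))
  m1 <- cluster_analytes(p, k = 1, seed = 1, n_restarts = 2)
  expect_true(all(m1$assignment$cluster == 1))
  m2 <- cluster_analytes(p, k = 2, seed = 1, n_restarts = 5)
  asg <- setNames(m2$assignment$cluster, m2$assignment$analyte)
  expect_equal(asg[["b"]], asg[["b_dup"]])  # identical points co-cluster
  expect_error(cluster_analytes(p, k = 10), "exceeds")
})

test_that("PC1 orientation is invariant to the decomposition sign", {
  set.seed(71)
  scores <- rnorm(30)
  loadings <- setNames(runif(8, 0.2, 0.5), paste0("a", 1:8))
  o1 <- sexdiffr:::orient_pc1(scores, loadings)
  o2 <- sexdiffr:::orient_pc1(-scores, -loadings)
  expect_identical(o1$scores, o2$scores)
  expect_identical(o1$loadings, o2$loadings)
  # positively-loaded component stays put, negated one is flipped back
  expect_identical(o1$scores, scores)
  expect_true(o2$flipped)
})

test_that("oriented composites are equivariant under global negation", {
  set.seed(73)
  n <- 40
  base <- rnorm(n)
  vals <- lapply(1:5, function(i) base + rnorm(n, sd = 0.4))
  names(vals) <- paste0("a", 1:5)
  p_pos <- toy_panel(values = vals, sex = rep(c("M", "F"), n / 2))
  p_neg <- toy_panel(values = lapply(vals, function(v) -v),
                     sex = rep(c("M", "F"), n / 2))
  model <- fixed_cluster_model(names(vals))
  s_pos <- composite_scores(p_pos, model, 1, "c1")
  s_neg <- composite_scores(p_neg, model, 1, "c1")
  expect_equal(s_neg$score, -s_pos$score, tolerance = 1e-10)
  # positively correlated cluster: oriented composite tracks the mean level
  zbar <- rowMeans(scale(do.call(cbind, vals)))
  expect_gt(cor(s_pos$score, zbar), 0.9)
})

test_that("identical per-cohort differences pool to themselves", {
  set.seed(79)
  mk <- function(coh, gap) {
    tibble::tibble(cohort_id = coh,
                   sex = rep(c("M", "F"), each = 20),
                   score = c(rnorm(20, gap, 1e-6), rnorm(20, 0, 1e-6)))
  }
  sc <- dplyr::bind_rows(mk("c1", 0.7), mk("c2", 0.7), mk("c3", 0.7))
  res <- pool_composite_difference(sc)
  expect_equal(res$pooled$delta_pooled, 0.7, tolerance = 1e-4)
  expect_equal(res$pooled$tau2, 0, tolerance = 1e-8)
  # fewer than three cohorts is flagged
  res2 <- pool_composite_difference(dplyr::bind_rows(mk("c1", 1)))
  expect_true(res2$pooled$excluded)
})

test_that("interaction ANOVA enforces a full 2x2 design", {
  sc <- tibble::tibble(
    sex = rep(c("M", "F"), 20),
    condition = rep(c("control", "case"), each = 20),
    score = rnorm(40)
  )
  res <- interaction_anova(sc)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$df1, 1)
  bad <- sc[!(sc$sex == "F" & sc$condition == "case"), ]
  expect_error(interaction_anova(bad), "empty design cell: F/case")
})

test_that("a noiseless planted interaction is flagged at the machine floor", {
  sc <- tibble::tibble(
    sex = rep(c("M", "F"), each = 10, times = 2),
    condition = rep(c("control", "case"), each = 20),
    score = rep(c(0, 0, 0, 1), each = 10)
  )
  res <- interaction_anova(sc)
  expect_true(res$degenerate)
  expect_lte(res$p, .Machine$double.xmin)
})

test_that("composite analysis assembles pooled differences and interactions", {
  d <- default_design(scale = 0.35, n_analytes = 30, k_true = 2,
                      lambda = 0.5, seed = 83)
  s <- simulate_study(d)
  model <- cluster_analytes(s$panel, k = 2, seed = 83, n_restarts = 10)
  res <- composite_analysis(s$panel, model, config = run_config(k = 2))
  expect_equal(nrow(res$clusters), 2)
  expect_equal(res$case_cohort, "cohort_10")
  expect_true(all(!is.na(res$clusters$interaction_p)))
  expect_equal(res$clusters$interaction_q,
               bh_adjust(res$clusters$interaction_p))
  expect_true(all(res$clusters$ci_low <= res$clusters$delta_pooled &
                    res$clusters$delta_pooled <= res$clusters$ci_high))
  # analyte map covers every clustered analyte
  am <- analyte_map(model)
  expect_setequal(am$analyte, model$assignment$analyte)
})
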