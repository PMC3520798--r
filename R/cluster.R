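#' Replace outlying cells before clustering
#'
#' Clustering is sensitive to extreme observations, so cells flagged by
#' the same rule as [remove_outliers()] (computed within the reference
#' cohort) are replaced by a uniform random draw between the minimum and
#' maximum of the analyte's non-outlying values. Deterministic under a
#' fixed seed. Analytes with fewer than 3 present values are skipped.
#'
#' @param mat Numeric matrix, analytes in rows, samples in columns
#'   (`NA` for absent cells).
#' @param sd_multiplier Outlier rule multiplier (default 4).
#' @param seed Integer seed for the replacement draws.
#' @return The matrix with outlying cells replaced.
#' @export
replace_outlying_for_clustering <- function(mat, sd_multiplier = 4,
                                            seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    present <- which(!is.na(v))
    if (length(present) < 3) next
    mu <- mean(v[present])
    s <- sd(v[present])
    if (!is.finite(s) || s == 0) next
    out <- present[abs(v[present] - mu) > sd_multiplier * s]
    if (!length(out)) next
    keep <- v[setdiff(present, out)]
    if (!length(keep)) next
    mat[i, out] <- runif(length(out), min(keep), max(keep))
  }
  mat
}

#' Cluster analytes on the reference cohort
#'
#' Groups analytes with similar concentration patterns by k-means on
#' standardized analyte levels measured in the reference cohort (by
#' default the largest cohort). Each analyte is a point in sample space:
#' its values are standardized to zero mean and unit SD within the
#' reference cohort (missing cells contribute 0 on the standardized
#' scale), outlying cells having first been replaced via
#' [replace_outlying_for_clustering()]. The best of `n_restarts`
#' random initialisations (lowest total within-cluster sum of squares,
#' ties broken by restart order) is kept.
#'
#' @param panel An [analyte_panel].
#' @param k Number of clusters (pre-specified default 6).
#' @param seed Integer seed (restart `i` uses `seed + i - 1`).
#' @param n_restarts Number of k-means restarts (default 50).
#' @param reference_cohort Cohort id; `NULL` picks the cohort with most
#'   samples (ties broken alphabetically).
#' @param sd_multiplier Outlier rule for the pre-clustering replacement.
#' @return An object of class `cluster_model`: list with `assignment`
#'   (tibble `analyte`, `cluster`), `reference_cohort`, `k`, `seed`,
#'   `n_restarts`, `tot_withinss`, and the standardized reference
#'   `matrix`.
#' @export
cluster_analytes <- function(panel, k = 6, seed = 1L, n_restarts = 50,
                             reference_cohort = NULL, sd_multiplier = 4) {
  if (is.null(reference_cohort)) {
    sizes <- panel$samples %>%
      count(.data$cohort_id) %>%
      arrange(desc(.data$n), .data$cohort_id)
    reference_cohort <- sizes$cohort_id[1]
  }
  mat <- t(panel_matrix(panel, cohort = reference_cohort))  # analyte x sample
  if (k > nrow(mat)) {
    abort(paste0("k = ", k, " exceeds the number of analytes (",
                 nrow(mat), ")"))
  }
  mat <- replace_outlying_for_clustering(mat, sd_multiplier, seed)
  z <- standardize_rows(mat)
  z[is.na(z)] <- 0

  best <- NULL
  for (i in seq_len(n_restarts)) {
    set.seed(seed + i - 1L)
    fit <- kmeans(z, centers = k, nstart = 1, iter.max = 100)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(
    assignment = tibble(analyte = rownames(z),
                        cluster = as.integer(best$cluster)),
    reference_cohort = reference_cohort,
    k = as.integer(k), seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    tot_withinss = best$tot.withinss,
    matrix = z
  ), class = "cluster_model")
}

standardize_rows <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  s <- apply(mat, 1, sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  (mat - mu) / s
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "on", x$reference_cohort, "\n")
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Oriented composite (PC1) scores for one cluster and cohort
#'
#' Summarises all analytes of a cluster in one composite variable: the
#' first principal component of the cluster's analytes standardized
#' within the cohort (missing cells 0-filled on the standardized scale).
#' Because the sign of a principal component is arbitrary, scores are
#' oriented by the average sign of the loadings of the top-loading
#' analytes (|loading| in the upper quartile, at least
#' `min_top` analytes): if that average sign is negative all scores and
#' loadings are flipped, so the composite tracks the average direction
#' of its dominant members. Scores are returned on the natural PC1
#' scale (their variance is the leading eigenvalue); the composite is a
#' plain linear summary of the standardized analytes, and no further
#' rescaling is applied.
#'
#' @param panel An [analyte_panel].
#' @param model A [cluster_analytes()] fit.
#' @param cluster Cluster label.
#' @param cohort Cohort id.
#' @param top_quantile Quantile of |loading| defining top-loading
#'   analytes.
#' @param min_top Minimum number of top-loading analytes.
#' @return A tibble `sample_id`, `cohort_id`, `sex`, `condition`,
#'   `score`, with attributes `loadings` (named, oriented) and
#'   `flipped`.
#' @export
composite_scores <- function(panel, model, cluster, cohort,
                             top_quantile = 0.75, min_top = 3) {
  analytes <- model$assignment %>%
    filter(.data$cluster == !!cluster) %>%
    pull(.data$analyte)
  samp <- panel$samples %>% filter(.data$cohort_id == cohort)
  if (!nrow(samp)) abort(paste0("no samples in cohort ", cohort))
  mat <- panel_matrix(panel, cohort = cohort)
  analytes <- intersect(analytes, colnames(mat))
  mat <- mat[, analytes, drop = FALSE]
  usable <- colSums(!is.na(mat)) >= 2 &
    apply(mat, 2, function(v) sd(v, na.rm = TRUE) > 0)
  usable[is.na(usable)] <- FALSE
  mat <- mat[, usable, drop = FALSE]
  if (ncol(mat) < 2) {
    abort(paste0("cluster ", cluster, " has fewer than 2 usable analytes",
                 " in cohort ", cohort))
  }
  z <- scale(mat)
  z[is.na(z)] <- 0
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  o <- orient_pc1(pc$x[, 1], pc$rotation[, 1], top_quantile, min_top)

  out <- samp %>%
    select("sample_id", "cohort_id", "sex", "condition") %>%
    mutate(score = o$scores[match(.data$sample_id, rownames(z))])
  attr(out, "loadings") <- o$loadings
  attr(out, "flipped") <- o$flipped
  out
}

## Resolve the arbitrary sign of a principal component: flip so the
## average loading sign of the top-|loading| analytes is positive.
## Invariant under (scores, loadings) -> (-scores, -loadings).
orient_pc1 <- function(scores, loadings, top_quantile = 0.75,
                       min_top = 3) {
  a <- abs(loadings)
  thr <- quantile(a, top_quantile)
  top <- names(a)[a >= thr]
  if (length(top) < min_top) {
    top <- names(sort(a, decreasing = TRUE))[seq_len(min(min_top,
                                                         length(a)))]
  }
  s <- sign(sum(sign(loadings[top])))
  if (s == 0) s <- sign(sum(loadings[top]))
  if (s == 0) s <- 1
  if (s < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = scores, loadings = loadings, flipped = s < 0)
}

#' Pool composite sex differences across cohorts
#'
#' For each cohort, the sex difference of the composite is the raw mean
#' difference `d_h = mean(male scores) - mean(female scores)` with
#' Welch-style variance `v_h = s2_m/n_m + s2_f/n_f`; the per-cohort
#' differences are pooled with the same DerSimonian-Laird random-effects
#' model as the analyte-level meta-analysis.
#'
#' @param scores Tibble with columns `cohort_id`, `sex`, `score` (rows
#'   from [composite_scores()] across cohorts).
#' @param min_cohorts Minimum number of cohorts (default 3).
#' @param level Confidence level.
#' @return A list with `cohorts` (per-cohort `d`, `v`, sizes) and
#'   `pooled` (one-row tibble from [pool_random_effects()], on the
#'   difference scale, CI not truncated).
#' @export
pool_composite_difference <- function(scores, min_cohorts = 3,
                                      level = 0.95) {
  per <- scores %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$cohort_id) %>%
    summarise(
      n_male = sum(.data$sex == "M"),
      n_female = sum(.data$sex == "F"),
      d = mean(.data$score[.data$sex == "M"]) -
        mean(.data$score[.data$sex == "F"]),
      v = var(.data$score[.data$sex == "M"]) / n_male +
        var(.data$score[.data$sex == "F"]) / n_female,
      .groups = "drop"
    ) %>%
    filter(.data$n_male >= 2, .data$n_female >= 2, .data$v > 0)
  pooled <- pool_random_effects(per$d, per$v, min_cohorts = min_cohorts,
                                level = level)
  if (!pooled$excluded) {
    # mean-difference scale is unbounded; undo the [-1, 1] truncation
    zc <- qnorm((1 + level) / 2)
    pooled$ci_low <- pooled$delta_pooled -
      zc * sqrt(pooled$variance_pooled)
    pooled$ci_high <- pooled$delta_pooled +
      zc * sqrt(pooled$variance_pooled)
  }
  list(cohorts = per, pooled = pooled)
}

#' Sex-by-condition interaction ANOVA on composite scores
#'
#' Two-way fixed-effects ANOVA (`score ~ sex * condition`) on oriented
#' composite scores from a control cohort and a case cohort; the
#' interaction F-test asks whether the male-female difference in the
#' composite differs between conditions. With zero residual variance
#' (degenerate data) the p-value is reported as the machine floor and
#' flagged.
#'
#' @param scores Tibble with columns `sex`, `condition`, `score`.
#' @return A one-row tibble `F_stat`, `p`, `df1`, `df2`, `degenerate`.
#' @export
interaction_anova <- function(scores) {
  scores <- scores %>% filter(!is.na(.data$score))
  cells <- table(scores$sex, scores$condition)
  if (nrow(cells) < 2 || ncol(cells) < 2 || any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- if (length(empty)) {
      paste0(rownames(cells)[empty[1, 1]], "/",
             colnames(cells)[empty[1, 2]])
    } else "missing sex or condition level"
    abort(paste0("interaction_anova: empty design cell: ", lab))
  }
  fit <- lm(score ~ sex * condition, data = scores)
  # a numerically perfect fit is handled below via the degenerate flag
  an <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  row <- "sex:condition"
  f_stat <- an[row, "F value"]
  p <- an[row, "Pr(>F)"]
  ms_res <- an["Residuals", "Mean Sq"]
  degenerate <- FALSE
  if (!is.finite(f_stat) || !is.finite(p) ||
      ms_res <= 1e-12 * mean(scores$score^2)) {
    # (numerically) zero residual variance: the cell means explain
    # everything, so the F statistic diverges
    degenerate <- TRUE
    f_stat <- Inf
    p <- .Machine$double.xmin
  }
  tibble(F_stat = f_stat, p = p,
         df1 = an[row, "Df"], df2 = an["Residuals", "Df"],
         degenerate = degenerate)
}

#' Cluster-level composite analysis
#'
#' For every cluster of a fitted [cluster_analytes()] model: computes
#' oriented composite scores per cohort, pools the male-minus-female
#' composite differences across control cohorts with a random-effects
#' model, and tests the sex-by-condition interaction between a
#' designated comparison (control) cohort and the case cohort.
#' Interaction p-values are Benjamini-Hochberg adjusted across
#' clusters.
#'
#' @param panel An [analyte_panel] containing control and case cohorts.
#' @param model A `cluster_model`.
#' @param case_cohort Cohort id of the disease group; `NULL` picks the
#'   cohort whose samples are `condition == "case"`.
#' @param comparison_cohort Control cohort for the ANOVA; `NULL` picks
#'   the control cohort with per-sex size closest to the case cohort's.
#' @param config A [run_config()] supplying `alpha`, `ci_level`,
#'   `min_cohorts` and the orientation parameters.
#' @return A list of class `composite_results`: `clusters` (one row per
#'   cluster: pooled difference, CI, tau2, interaction F/p/q),
#'   `cohort_differences` (per cluster x cohort `d`, `v`), and `scores`
#'   (all per-sample composite scores).
#' @export
composite_analysis <- function(panel, model, case_cohort = NULL,
                               comparison_cohort = NULL,
                               config = run_config()) {
  cohorts <- panel_cohorts(panel)
  if (is.null(case_cohort)) {
    cc <- cohorts %>% filter(.data$condition == "case")
    case_cohort <- if (nrow(cc)) cc$cohort_id[1] else NULL
  }
  controls <- cohorts %>% filter(.data$condition == "control")
  if (is.null(comparison_cohort) && !is.null(case_cohort)) {
    case_n <- cohorts %>% filter(.data$cohort_id == case_cohort)
    comparison_cohort <- controls %>%
      mutate(gap = abs(.data$n_male - case_n$n_male[1]) +
               abs(.data$n_female - case_n$n_female[1])) %>%
      arrange(.data$gap, .data$cohort_id) %>%
      slice(1) %>% pull(.data$cohort_id)
  }

  clusters <- sort(unique(model$assignment$cluster))
  all_scores <- list()
  rows <- list()
  per_cohort <- list()
  for (cl in clusters) {
    sc <- purrr::map(controls$cohort_id, function(coh) {
      tryCatch(
        composite_scores(panel, model, cl, coh,
                         top_quantile = config$top_loading_quantile,
                         min_top = config$min_top_loadings),
        error = function(e) NULL)
    })
    sc <- bind_rows(sc)
    pooled <- pool_composite_difference(sc,
                                        min_cohorts = config$min_cohorts,
                                        level = config$ci_level)
    inter <- tibble(F_stat = NA_real_, p = NA_real_, degenerate = NA)
    if (!is.null(case_cohort)) {
      sc_case <- tryCatch(
        composite_scores(panel, model, cl, case_cohort,
                         top_quantile = config$top_loading_quantile,
                         min_top = config$min_top_loadings),
        error = function(e) NULL)
      sc_ctrl <- sc %>% filter(.data$cohort_id == comparison_cohort)
      if (!is.null(sc_case) && nrow(sc_ctrl)) {
        inter <- interaction_anova(bind_rows(sc_ctrl, sc_case)) %>%
          select("F_stat", "p", "degenerate")
        sc <- bind_rows(sc, sc_case)
      }
    }
    all_scores[[as.character(cl)]] <- sc %>% mutate(cluster = cl)
    per_cohort[[as.character(cl)]] <- pooled$cohorts %>%
      mutate(cluster = cl, .before = 1)
    rows[[as.character(cl)]] <- pooled$pooled %>%
      mutate(cluster = cl, .before = 1) %>%
      bind_cols(inter %>%
                  rename(interaction_F = "F_stat", interaction_p = "p"))
  }
  out <- bind_rows(rows) %>%
    mutate(interaction_q = bh_adjust(.data$interaction_p))
  structure(list(
    clusters = out,
    cohort_differences = bind_rows(per_cohort),
    scores = bind_rows(all_scores),
    case_cohort = case_cohort,
    comparison_cohort = comparison_cohort,
    alpha = config$alpha
  ), class = "composite_results")
}

#' @export
print.composite_results <- function(x, ...) {
  cat("<composite_results> case:", x$case_cohort %||% "none",
      " comparison:", x$comparison_cohort %||% "none", "\n")
  print(x$clusters %>%
          select("cluster", "k", "delta_pooled", "ci_low", "ci_high",
                 "interaction_p", "interaction_q"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-dimensional analyte map
#'
#' Descriptive export mirroring a PCA overview plot: analytes as
#' observations over the reference cohort's samples, projected on the
#' first two principal components, with cluster labels and (optionally)
#' meta-analysis significance.
#'
#' @param model A `cluster_model`.
#' @param pooled Optional [run_meta()] table to attach `q` and
#'   `significant` flags.
#' @return A tibble `analyte`, `dim1`, `dim2`, `cluster` (+ `q`,
#'   `significant`, `direction` when `pooled` is given).
#' @export
analyte_map <- function(model, pooled = NULL) {
  pc <- prcomp(model$matrix, center = FALSE, scale. = FALSE)
  out <- tibble(analyte = rownames(model$matrix),
                dim1 = pc$x[, 1], dim2 = pc$x[, 2]) %>%
    left_join(model$assignment, by = "analyte")
  if (!is.null(pooled)) {
    out <- out %>%
      left_join(pooled %>%
                  select("analyte", "q", "significant", "direction"),
                by = "analyte")
  }
  out
}
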