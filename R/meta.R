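#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-cohort effect estimates allowing the cohort-specific true
#' effects to vary around a common mean with between-cohort variance
#' `tau^2`. With fixed-effect weights `w_i = 1/v_i`:
#' `delta_FE = sum(w d)/sum(w)`, Cochran's
#' `Q = sum(w (d - delta_FE)^2)`,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and the
#' random-effects weights `w*_i = 1/(v_i + tau2)` give the pooled
#' estimate, its variance `1/sum(w*)`, a normal z test, and a confidence
#' interval truncated to `[-1, 1]` (the Cliff's delta scale).
#'
#' @param delta Numeric vector of per-cohort effect estimates.
#' @param variance Positive per-cohort sampling variances.
#' @param min_cohorts Minimum number of cohorts required (default 3);
#'   fewer returns a one-row tibble with `excluded = TRUE` and `NA`
#'   statistics.
#' @param level Confidence level.
#' @return A one-row tibble: `k`, `delta_pooled`, `variance_pooled`,
#'   `ci_low`, `ci_high`, `z`, `p`, `Q`, `tau2`, `p_het`, `excluded`.
#' @export
pool_random_effects <- function(delta, variance, min_cohorts = 3,
                                level = 0.95) {
  if (length(delta) != length(variance)) {
    abort("pool_random_effects: delta and variance lengths differ")
  }
  k <- length(delta)
  if (k < min_cohorts) {
    return(tibble(k = k, delta_pooled = NA_real_,
                  variance_pooled = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, z = NA_real_, p = NA_real_,
                  Q = NA_real_, tau2 = NA_real_, p_het = NA_real_,
                  excluded = TRUE))
  }
  if (any(variance <= 0)) {
    abort("pool_random_effects: all variances must be > 0")
  }
  w <- 1 / variance
  d_fe <- sum(w * delta) / sum(w)
  q_stat <- sum(w * (delta - d_fe)^2)
  c_const <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q_stat - (k - 1)) / c_const)
  ws <- 1 / (variance + tau2)
  dp <- sum(ws * delta) / sum(ws)
  vp <- 1 / sum(ws)
  z <- dp / sqrt(vp)
  zc <- qnorm((1 + level) / 2)
  tibble(k = k, delta_pooled = dp, variance_pooled = vp,
         ci_low = max(-1, dp - zc * sqrt(vp)),
         ci_high = min(1, dp + zc * sqrt(vp)),
         z = z, p = 2 * pnorm(-abs(z)),
         Q = q_stat, tau2 = tau2,
         p_het = heterogeneity_test(q_stat, k),
         excluded = FALSE)
}

#' Chi-squared heterogeneity test
#'
#' Upper-tail probability of Cochran's Q under the chi-squared
#' distribution with `k - 1` degrees of freedom (the homogeneity null).
#'
#' @param Q Heterogeneity statistic (>= 0).
#' @param k Number of cohorts pooled (>= 2).
#' @return The p-value.
#' @export
heterogeneity_test <- function(Q, k) {
  if (any(k < 2)) abort("heterogeneity_test: k must be >= 2")
  pchisq(Q, df = k - 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sorting the p-values
#' ascending, `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, mapped
#' back to the input order. Delegates to [stats::p.adjust()] after
#' validating the input.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return The q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Pool per-cohort effects across analytes
#'
#' Applies [pool_random_effects()] to every analyte in a long effect
#' table, tests heterogeneity, adjusts all pooled p-values with
#' [bh_adjust()], and labels each analyte's direction (`male_higher`
#' for a positive pooled delta, `female_higher` for a negative one).
#' Analytes measurable in fewer than `min_cohorts` cohorts are retained
#' in the output with `excluded = TRUE` rather than silently dropped.
#'
#' @param effects Long tibble from [cohort_effects()].
#' @param alpha Significance level applied to q-values.
#' @param min_cohorts Minimum cohort count per analyte (default 3).
#' @param level Confidence level.
#' @return A tibble of class `pooled_effects`, one row per analyte,
#'   ordered by q then analyte, with a `significant` flag at
#'   `q < alpha`.
#' @export
run_meta <- function(effects, alpha = 0.05, min_cohorts = 3,
                     level = 0.95) {
  if (is.null(effects) || !nrow(effects)) {
    abort("run_meta: empty effect table")
  }
  pooled <- effects %>%
    group_by(.data$analyte) %>%
    group_modify(~ pool_random_effects(.x$delta, .x$variance,
                                       min_cohorts = min_cohorts,
                                       level = level)) %>%
    ungroup()
  pooled$q <- NA_real_
  inc <- !pooled$excluded
  pooled$q[inc] <- bh_adjust(pooled$p[inc])
  pooled <- pooled %>%
    mutate(direction = case_when(
      .data$excluded ~ NA_character_,
      .data$delta_pooled > 0 ~ "male_higher",
      .data$delta_pooled < 0 ~ "female_higher",
      TRUE ~ "none"
    ),
    significant = !.data$excluded & .data$q < alpha) %>%
    arrange(.data$excluded, .data$q, .data$analyte)
  class(pooled) <- c("pooled_effects", class(pooled))
  attr(pooled, "alpha") <- alpha
  pooled
}
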