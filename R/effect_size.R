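#' Cliff's delta
#'
#' Nonparametric effect size for a male-versus-female comparison:
#' `delta = P(X > Y) - P(X < Y)`, estimated by the mean of
#' `sign(x_i - y_j)` over all pairs. Positive values mean the analyte is
#' higher in males (`x`); ties contribute zero. Computed in
#' `O((m + n) log(m + n))` from midranks — with average ranks the
#' Mann-Whitney statistic `U = sum(rank(x in pooled)) - m(m+1)/2` equals
#' `#\{x > y\} + #\{x = y\}/2`, so `delta = (2U - mn) / (mn)` reproduces the
#' pairwise sign count exactly (midranks are multiples of 1/2, so the
#' arithmetic is exact in doubles).
#'
#' @param x Numeric vector for the first (male) group; `NA`s dropped.
#' @param y Numeric vector for the second (female) group; `NA`s dropped.
#' @return A single number in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort("cliffs_delta: both groups must be non-empty after removing NAs")
  }
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  (2 * u - m * n) / (m * n)
}

#' Sampling variance of Cliff's delta
#'
#' Cliff's consistent variance estimator. With dominance entries
#' `d_ij = sign(x_i - y_j)`, row means `d_i.`, and column means `d_.j`:
#' \deqn{v = \frac{n^2 \sum_i (d_{i\cdot}-\delta)^2 +
#'                m^2 \sum_j (d_{\cdot j}-\delta)^2 -
#'                \sum_{ij} (d_{ij}-\delta)^2}{m n (m-1)(n-1)}.}
#' All terms are obtained from rank counts in
#' `O((m + n) log(m + n))`, without forming the dominance matrix
#' (`sum d_ij^2 = mn - #ties`). When the formula returns a non-positive
#' value for non-degenerate data the floor `(1 - delta^2)/(mn - 1)` is
#' used, and at complete separation (`|delta| = 1`, where that floor is
#' zero) the floor is evaluated at the continuity-shrunk delta
#' `(mn - 1)/mn`, keeping meta-analysis weights finite.
#'
#' @inheritParams cliffs_delta
#' @param delta Optional precomputed Cliff's delta for `x`, `y`.
#' @return A single non-negative variance.
#' @export
delta_variance <- function(x, y, delta = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  m <- length(x)
  n <- length(y)
  if (m < 2 || n < 2) {
    abort("delta_variance: need at least 2 observations per group")
  }
  st <- cliff_stats(x, y)
  if (!is.null(delta) && abs(delta - st$delta) > 1e-12) {
    abort("delta_variance: supplied delta does not match the data")
  }
  st$variance
}

## delta + consistent variance from rank counts, shared by the exported
## functions and the per-cohort sweep.
cliff_stats <- function(x, y) {
  m <- length(x)
  n <- length(y)
  sx <- sort(x)
  sy <- sort(y)
  lt_x <- findInterval(x, sy, left.open = TRUE)   # |y <  x_i|
  le_x <- findInterval(x, sy)                     # |y <= x_i|
  di <- (lt_x + le_x - n) / n                     # row means d_i.
  lt_y <- findInterval(y, sx, left.open = TRUE)   # |x <  y_j|
  le_y <- findInterval(y, sx)                     # |x <= y_j|
  dj <- (m - lt_y - le_y) / m                     # column means d_.j
  # sum(lt_x) + sum(le_x) = 2|x > y| + |x = y|: exact integer arithmetic
  delta <- (sum(lt_x) + sum(le_x) - m * n) / (m * n)

  if (m < 2 || n < 2) return(list(delta = delta, variance = NA_real_))

  shared <- intersect(x, y)
  n_ties <- if (length(shared)) {
    sum(vapply(shared, function(v) sum(x == v) * sum(y == v), numeric(1)))
  } else 0
  s_tot <- (m * n - n_ties) - m * n * delta^2     # sum (d_ij - delta)^2
  s_row <- sum((di - delta)^2)
  s_col <- sum((dj - delta)^2)
  v <- (n^2 * s_row + m^2 * s_col - s_tot) /
    (m * n * (m - 1) * (n - 1))
  if (v <= 0) {
    v <- if (abs(delta) >= 1) {
      d_shrunk <- (m * n - 1) / (m * n)
      (1 - d_shrunk^2) / (m * n - 1)
    } else {
      (1 - delta^2) / (m * n - 1)
    }
  }
  list(delta = delta, variance = v, n_male = m, n_female = n)
}

#' Normal-approximation confidence interval for Cliff's delta
#'
#' `delta +/- z * sqrt(variance)`, truncated to `[-1, 1]`.
#'
#' @param delta Effect estimate.
#' @param variance Its sampling variance (>= 0).
#' @param level Confidence level in (0, 1).
#' @return A named numeric vector `c(ci_low, ci_high)`.
#' @export
delta_ci <- function(delta, variance, level = 0.95) {
  if (any(variance < 0)) abort("delta_ci: variance must be non-negative")
  if (level <= 0 || level >= 1) abort("delta_ci: level must be in (0, 1)")
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(variance)
  c(ci_low = pmax(-1, delta - half), ci_high = pmin(1, delta + half))
}

#' Per-cohort Cliff's delta effect table
#'
#' Computes, for every analyte within every cohort, the male-versus-
#' female Cliff's delta, its consistent variance, and a normal
#' confidence interval. Only `OK` cells enter (pairwise-complete; no
#' imputation); cohort-analyte combinations with fewer than 2 usable
#' values in either sex are skipped.
#'
#' @param panel An [analyte_panel] (typically after
#'   [preprocess_panel()]).
#' @param cohorts Optional cohort ids to restrict to (default: all
#'   cohorts whose samples are controls).
#' @param level Confidence level.
#' @return A tibble with columns `analyte`, `cohort_id`, `n_male`,
#'   `n_female`, `delta`, `variance`, `ci_low`, `ci_high`.
#' @export
cohort_effects <- function(panel, cohorts = NULL, level = 0.95) {
  if (is.null(cohorts)) {
    cohorts <- panel$samples %>%
      filter(.data$condition == "control") %>%
      pull(.data$cohort_id) %>% unique() %>% sort()
  }
  z <- qnorm((1 + level) / 2)
  res <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    coh <- cohorts[ci]
    samp <- panel$samples %>% filter(.data$cohort_id == coh)
    mat <- panel_matrix(panel, cohort = coh)
    is_m <- samp$sex[match(rownames(mat), samp$sample_id)] == "M"
    n_a <- ncol(mat)
    nm <- nf <- integer(n_a)
    dl <- vr <- rep(NA_real_, n_a)
    for (j in seq_len(n_a)) {
      v <- mat[, j]
      x <- v[is_m & !is.na(v)]
      y <- v[!is_m & !is.na(v)]
      if (length(x) < 2 || length(y) < 2) next
      st <- cliff_stats(x, y)
      nm[j] <- st$n_male; nf[j] <- st$n_female
      dl[j] <- st$delta; vr[j] <- st$variance
    }
    ok <- !is.na(dl)
    res[[ci]] <- tibble(analyte = colnames(mat)[ok], cohort_id = coh,
                        n_male = nm[ok], n_female = nf[ok],
                        delta = dl[ok], variance = vr[ok])
  }
  out <- bind_rows(res)
  if (!nrow(out)) abort("cohort_effects: no cohort-analyte pair had >= 2 usable values per sex")
  out %>%
    mutate(half = z * sqrt(.data$variance),
           ci_low = pmax(-1, .data$delta - .data$half),
           ci_high = pmin(1, .data$delta + .data$half)) %>%
    select(-"half") %>%
    arrange(.data$analyte, .data$cohort_id)
}
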