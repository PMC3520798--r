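#' Match males and females within each cohort
#'
#' Greedy 1:1 male-female pairing minimising a Gower-style distance over
#' the chosen covariates: numeric covariates contribute the absolute
#' difference divided by the within-cohort range, categorical covariates
#' a 0/1 mismatch. Covariates missing for either member of a candidate
#' pair (or with zero within-cohort range) are skipped, with weight
#' renormalisation. Candidate pairs are sorted by distance (ties broken
#' by sample id) and accepted greedily while disjoint; unmatched samples
#' are removed, so every retained cohort has equal male and female
#' counts.
#'
#' @param panel An [analyte_panel].
#' @param covariates Ordered covariate names to match on (only those
#'   present in the panel are used).
#' @return A list with the matched `panel`, a `report` tibble (per
#'   cohort: `n_pairs`, `n_discarded`), and a `pairs` tibble
#'   (`cohort_id`, `male_id`, `female_id`, `distance`).
#' @export
match_sexes <- function(panel, covariates = default_covariates) {
  covs <- intersect(covariates, names(panel$samples))
  keep_ids <- character(0)
  report <- list()
  pairs_out <- list()
  for (coh in sort(unique(panel$samples$cohort_id))) {
    s <- panel$samples %>% filter(.data$cohort_id == coh)
    males <- s %>% filter(.data$sex == "M")
    females <- s %>% filter(.data$sex == "F")
    if (!nrow(males) || !nrow(females)) {
      warn(paste0("cohort ", coh, " lacks one sex entirely; dropped"))
      report[[coh]] <- tibble(cohort_id = coh, n_pairs = 0L,
                              n_discarded = nrow(s))
      next
    }
    d <- gower_pairs(males, females, s, covs)
    d <- d[order(d$dist, d$male_id, d$female_id), ]
    used_m <- character(0); used_f <- character(0)
    acc <- integer(0)
    for (i in seq_len(nrow(d))) {
      mi <- d$male_id[i]; fi <- d$female_id[i]
      if (mi %in% used_m || fi %in% used_f) next
      used_m <- c(used_m, mi); used_f <- c(used_f, fi)
      acc <- c(acc, i)
    }
    keep_ids <- c(keep_ids, used_m, used_f)
    pairs_out[[coh]] <- d[acc, ] %>%
      mutate(cohort_id = coh, .before = 1) %>%
      rename(distance = "dist")
    report[[coh]] <- tibble(cohort_id = coh, n_pairs = length(acc),
                            n_discarded = nrow(s) - 2L * length(acc))
  }
  samples <- panel$samples %>% filter(.data$sample_id %in% keep_ids)
  measurements <- panel$measurements %>%
    filter(.data$sample_id %in% keep_ids)
  list(panel = new_panel(samples, measurements),
       report = bind_rows(report),
       pairs = bind_rows(pairs_out))
}

## All male x female Gower distances within one cohort.
gower_pairs <- function(males, females, cohort_samples, covs) {
  grid <- tidyr::expand_grid(male_id = males$sample_id,
                             female_id = females$sample_id)
  if (!length(covs)) {
    grid$dist <- 0
    return(grid)
  }
  total <- matrix(0, nrow(males), nrow(females))
  wsum <- matrix(0, nrow(males), nrow(females))
  for (cv in covs) {
    vm <- males[[cv]]; vf <- females[[cv]]
    if (is.numeric(cohort_samples[[cv]])) {
      rng <- diff(range(cohort_samples[[cv]], na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) next  # degenerate range: skip
      contrib <- abs(outer(vm, vf, "-")) / rng
    } else {
      contrib <- outer(vm, vf, "!=") * 1
    }
    ok <- !is.na(contrib)
    contrib[!ok] <- 0
    total <- total + contrib
    wsum <- wsum + ok
  }
  d <- ifelse(wsum > 0, total / wsum, 0)
  grid$dist <- as.vector(t(d))  # expand_grid varies female_id fastest
  grid
}

#' Replace out-of-range assay values
#'
#' Cells censored below the assay range are set to half the minimum
#' value measured for that analyte; cells above the range to double the
#' maximum. Minima and maxima are taken over the analyte's `OK` cells
#' across the whole panel. Replaced cells become `OK`; `MISSING` cells
#' are untouched. An analyte with out-of-range cells but no `OK` cell is
#' left unreplaced and flagged in the report.
#'
#' @param panel An [analyte_panel].
#' @return A list with the updated `panel` and a per-analyte `report`
#'   tibble (`n_low`, `n_high`, `unreplaceable`).
#' @export
replace_out_of_range <- function(panel) {
  m <- panel$measurements
  stats <- m %>%
    filter(.data$status == "OK") %>%
    group_by(.data$analyte) %>%
    summarise(min_ok = min(.data$value), max_ok = max(.data$value),
              .groups = "drop")
  m <- m %>% left_join(stats, by = "analyte")
  low <- m$status == "BELOW_RANGE" & !is.na(m$min_ok)
  high <- m$status == "ABOVE_RANGE" & !is.na(m$max_ok)
  m$value[low] <- m$min_ok[low] / 2
  m$value[high] <- 2 * m$max_ok[high]
  m$status[low | high] <- "OK"
  report <- tibble(analyte = m$analyte, low = low, high = high,
                   still_oor = m$status %in%
                     c("BELOW_RANGE", "ABOVE_RANGE")) %>%
    group_by(.data$analyte) %>%
    summarise(n_low = sum(.data$low), n_high = sum(.data$high),
              unreplaceable = any(.data$still_oor), .groups = "drop")
  m <- m %>% select(-"min_ok", -"max_ok")
  list(panel = new_panel(panel$samples, m), report = report)
}

#' Eliminate analytes with excessive missingness
#'
#' Removes analytes whose fraction of `MISSING` cells over all retained
#' samples strictly exceeds `threshold`. Run after
#' [replace_out_of_range()], so replaced cells count as present; only
#' truly unmeasured cells count as missing.
#'
#' @param panel An [analyte_panel].
#' @param threshold Fraction in (0, 1]; the pre-specified default is
#'   0.70.
#' @return A list with the filtered `panel` and a per-analyte `report`
#'   tibble (`missing_fraction`, `dropped`).
#' @export
filter_missing_analytes <- function(panel, threshold = 0.70) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  report <- panel$measurements %>%
    group_by(.data$analyte) %>%
    summarise(missing_fraction = mean(.data$status == "MISSING"),
              .groups = "drop") %>%
    mutate(dropped = .data$missing_fraction > threshold)
  keep <- report$analyte[!report$dropped]
  m <- panel$measurements %>% filter(.data$analyte %in% keep)
  list(panel = new_panel(panel$samples, m), report = report)
}

#' Exclude extreme outlying measurements
#'
#' Single-pass rule per analyte: compute the mean and SD over all
#' present (`OK`) values pooled across cohorts, and set cells with
#' `|x - mean| > sd_multiplier * SD` to `OUTLIER_REMOVED` (treated as
#' missing downstream). Analytes with zero SD or fewer than 3 present
#' values are left untouched. The rule is not iterated.
#'
#' @param panel An [analyte_panel].
#' @param sd_multiplier Positive multiplier; the pre-specified default
#'   is 4.
#' @return A list with the updated `panel` and a per-analyte `report`
#'   tibble (`n_outliers_removed`).
#' @export
remove_outliers <- function(panel, sd_multiplier = 4) {
  if (sd_multiplier <= 0) abort("sd_multiplier must be > 0")
  m <- panel$measurements
  stats <- m %>%
    filter(.data$status == "OK") %>%
    group_by(.data$analyte) %>%
    summarise(mean_ok = mean(.data$value), sd_ok = sd(.data$value),
              n_ok = n(), .groups = "drop")
  m <- m %>% left_join(stats, by = "analyte")
  out <- m$status == "OK" & m$n_ok >= 3 & !is.na(m$sd_ok) & m$sd_ok > 0 &
    abs(m$value - m$mean_ok) > sd_multiplier * m$sd_ok
  m$status[out] <- "OUTLIER_REMOVED"
  m$value[out] <- NA_real_
  report <- tibble(analyte = m$analyte, removed = out) %>%
    group_by(.data$analyte) %>%
    summarise(n_outliers_removed = sum(.data$removed), .groups = "drop")
  m <- m %>% select(-"mean_ok", -"sd_ok", -"n_ok")
  list(panel = new_panel(panel$samples, m), report = report)
}

#' Run the full pre-processing pipeline
#'
#' Applies, in this fixed order: [match_sexes()] →
#' [replace_out_of_range()] → [filter_missing_analytes()] →
#' [remove_outliers()]. The order matters: replaced out-of-range cells
#' count as present for the missingness rule, and outlier statistics are
#' computed on the post-replacement values of the retained analytes.
#'
#' @param panel An [analyte_panel].
#' @param config A [run_config()].
#' @return A list with the processed `panel` and a `report` list holding
#'   the four per-stage report tibbles.
#' @export
preprocess_panel <- function(panel, config = run_config()) {
  st1 <- match_sexes(panel, config$covariates)
  st2 <- replace_out_of_range(st1$panel)
  st3 <- filter_missing_analytes(st2$panel, config$missing_threshold)
  st4 <- remove_outliers(st3$panel, config$sd_multiplier)
  list(panel = st4$panel,
       report = list(matching = st1$report,
                     replacement = st2$report,
                     missingness = st3$report,
                     outliers = st4$report))
}
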