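#' Analysis configuration
#'
#' Collects the fixed constants of the pipeline in one validated object.
#' The defaults encode the study's pre-specified choices: analytes with
#' more than 70% missing cells are dropped, values more than 4 standard
#' deviations from the overall mean are excluded, analytes are grouped
#' into k = 6 clusters on the largest cohort, and significance is read
#' off Benjamini-Hochberg q-values at alpha = 0.05.
#'
#' @param missing_threshold Fraction in (0, 1]; analytes whose missing
#'   fraction strictly exceeds it are eliminated.
#' @param sd_multiplier Positive multiplier for the outlier rule
#'   (`|x - mean| > sd_multiplier * SD`).
#' @param k Number of analyte clusters (>= 2).
#' @param alpha Significance level applied to q-values, in (0, 1).
#' @param ci_level Confidence level for intervals, in (0, 1).
#' @param min_cohorts Minimum number of cohorts an analyte must be
#'   measurable in to enter the meta-analysis (default 3).
#' @param n_restarts Random k-means restarts.
#' @param seed Integer seed governing every stochastic stage.
#' @param reference_cohort Cohort used to fit the cluster model; `NULL`
#'   selects the largest cohort.
#' @param case_cohort Cohort holding the disease group; `NULL` selects
#'   the cohort whose samples have `condition == "case"`.
#' @param comparison_cohort Control cohort entering the sex-by-condition
#'   ANOVA; `NULL` selects the control cohort whose per-sex size is
#'   closest to the case cohort's.
#' @param covariates Ordered covariate names used for male-female
#'   matching.
#' @param top_loading_quantile Quantile of |loading| defining the
#'   "top-loading" analytes used to orient composite scores.
#' @param min_top_loadings Minimum number of top-loading analytes.
#' @param scale Fraction in (0, 1] rescaling the synthetic study design.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(missing_threshold = 0.70,
                       sd_multiplier = 4,
                       k = 6,
                       alpha = 0.05,
                       ci_level = 0.95,
                       min_cohorts = 3,
                       n_restarts = 50,
                       seed = 1L,
                       reference_cohort = NULL,
                       case_cohort = NULL,
                       comparison_cohort = NULL,
                       covariates = default_covariates,
                       top_loading_quantile = 0.75,
                       min_top_loadings = 3,
                       scale = 1) {
  chk_frac <- function(x, name, lo_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        x <= 0 || x > 1) {
      abort(paste0("config field '", name, "' must be in (0, 1]: got ",
                   deparse(x)))
    }
  }
  chk_frac(missing_threshold, "missing_threshold")
  chk_frac(scale, "scale")
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0) {
    abort("config field 'sd_multiplier' must be > 0")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k)) {
    abort("config field 'k' must be an integer >= 2")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort(paste0("config field 'alpha' must be in (0, 1): got ",
                 deparse(alpha)))
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("config field 'ci_level' must be in (0, 1)")
  }
  if (!is.numeric(min_cohorts) || min_cohorts < 2) {
    abort("config field 'min_cohorts' must be >= 2")
  }
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    abort("config field 'n_restarts' must be >= 1")
  }
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort("config field 'seed' must be an explicit integer")
  }
  if (!is.numeric(top_loading_quantile) || top_loading_quantile <= 0 ||
      top_loading_quantile >= 1) {
    abort("config field 'top_loading_quantile' must be in (0, 1)")
  }
  structure(list(
    missing_threshold = missing_threshold,
    sd_multiplier = sd_multiplier,
    k = as.integer(k),
    alpha = alpha,
    ci_level = ci_level,
    min_cohorts = as.integer(min_cohorts),
    n_restarts = as.integer(n_restarts),
    seed = as.integer(seed),
    reference_cohort = reference_cohort,
    case_cohort = case_cohort,
    comparison_cohort = comparison_cohort,
    covariates = covariates,
    top_loading_quantile = top_loading_quantile,
    min_top_loadings = as.integer(min_top_loadings),
    scale = scale
  ), class = "run_config")
}

#' Validate a raw key-value configuration
#'
#' Fills defaults for absent keys and rejects invalid or unknown fields
#' with a message naming the offending field.
#'
#' @param raw A named list (e.g. parsed from YAML).
#' @return A validated `run_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config must be a named list")
  unknown <- setdiff(names(raw), names(formals(run_config)))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", toString(unknown)))
  }
  do.call(run_config, raw)
}

#' @rdname validate_config
#' @param path Path to a YAML configuration file with flat keys.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  validate_config(yaml::read_yaml(path))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) {
    cat("  ", nm, ": ", toString(flat[[nm]]), "\n", sep = "")
  }
  invisible(x)
}
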