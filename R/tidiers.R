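#' Tidy and summarise fitted pipeline objects
#'
#' broom-style methods. `tidy()` returns one row per estimated quantity
#' (analyte, cluster, ...); `glance()` returns a one-row summary of the
#' whole fit.
#'
#' @param x A `pooled_effects`, `cluster_model`, `composite_results`, or
#'   `study_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @name sexdiffr-tidiers
NULL

#' @rdname sexdiffr-tidiers
#' @method tidy pooled_effects
#' @export
tidy.pooled_effects <- function(x, ...) {
  as_tibble(x) %>%
    select("analyte", "k", estimate = "delta_pooled",
           "ci_low", "ci_high", "p", "q", "Q", "tau2", "p_het",
           "direction", "significant", "excluded")
}

#' @rdname sexdiffr-tidiers
#' @method glance pooled_effects
#' @export
glance.pooled_effects <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(
    n_analytes = nrow(x),
    n_pooled = sum(!x$excluded),
    n_excluded = sum(x$excluded),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_male_higher = sum(x$significant & x$direction == "male_higher",
                        na.rm = TRUE),
    n_female_higher = sum(x$significant & x$direction == "female_higher",
                          na.rm = TRUE),
    alpha = alpha
  )
}

#' @rdname sexdiffr-tidiers
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  as_tibble(x$assignment)
}

#' @rdname sexdiffr-tidiers
#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble(k = x$k, n_analytes = nrow(x$assignment),
         reference_cohort = x$reference_cohort,
         tot_withinss = x$tot_withinss, n_restarts = x$n_restarts)
}

#' @rdname sexdiffr-tidiers
#' @method tidy composite_results
#' @export
tidy.composite_results <- function(x, ...) {
  x$clusters %>%
    select("cluster", "k", estimate = "delta_pooled", "ci_low",
           "ci_high", "tau2", "interaction_F", "interaction_p",
           "interaction_q")
}

#' @rdname sexdiffr-tidiers
#' @method glance composite_results
#' @export
glance.composite_results <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         case_cohort = x$case_cohort %||% NA_character_,
         comparison_cohort = x$comparison_cohort %||% NA_character_,
         min_interaction_q = suppressWarnings(
           min(x$clusters$interaction_q, na.rm = TRUE)))
}

#' @rdname sexdiffr-tidiers
#' @method tidy study_run
#' @export
tidy.study_run <- function(x, ...) {
  tidy(x$pooled)
}

#' @rdname sexdiffr-tidiers
#' @method glance study_run
#' @export
glance.study_run <- function(x, ...) {
  bind_cols(glance(x$pooled),
            tibble(samples_retained = x$manifest$counts$samples_retained,
                   analytes_retained =
                     x$manifest$counts$analytes_retained))
}
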