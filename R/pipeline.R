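#' Run the full multi-cohort analysis pipeline
#'
#' Orchestrates every stage in fixed order: (optional) simulation →
#' pre-processing ([preprocess_panel()]) → per-cohort effect sizes
#' ([cohort_effects()], control cohorts only) → random-effects
#' meta-analysis with FDR control ([run_meta()]) → analyte clustering on
#' the largest cohort ([cluster_analytes()]) → composite scores, pooled
#' composite sex differences, and the sex-by-condition interaction test
#' ([composite_analysis()]). Inputs are never modified in place, and the
#' whole run is a pure function of (panel, config, seed).
#'
#' @param config A [run_config()].
#' @param panel An [analyte_panel]; if `NULL`, a synthetic study is
#'   simulated from [default_design()] at `config$scale` and
#'   `config$seed`.
#' @param design Optional `simulation_design` overriding the default
#'   when `panel` is `NULL`.
#' @return A list of class `study_run` with elements `panel` (processed),
#'   `preprocess_report`, `effects`, `pooled`, `cluster_model`,
#'   `composites`, `truth` (when simulated), and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), panel = NULL,
                         design = NULL) {
  config <- validate_config(unclass(config))
  truth <- NULL
  if (is.null(panel)) {
    if (is.null(design)) {
      design <- default_design(scale = config$scale, seed = config$seed)
    }
    sim <- simulate_study(design, seed = config$seed)
    panel <- sim$panel
    truth <- sim$truth
  }
  n_input <- nrow(panel$samples)

  pre <- preprocess_panel(panel, config)
  effects <- cohort_effects(pre$panel, level = config$ci_level)
  pooled <- run_meta(effects, alpha = config$alpha,
                     min_cohorts = config$min_cohorts,
                     level = config$ci_level)

  ref <- config$reference_cohort
  if (is.null(ref)) {
    ctl <- pre$panel$samples %>% filter(.data$condition == "control")
    sizes <- ctl %>% count(.data$cohort_id) %>%
      arrange(desc(.data$n), .data$cohort_id)
    ref <- sizes$cohort_id[1]
  }
  model <- cluster_analytes(pre$panel, k = config$k, seed = config$seed,
                            n_restarts = config$n_restarts,
                            reference_cohort = ref,
                            sd_multiplier = config$sd_multiplier)
  composites <- composite_analysis(pre$panel, model,
                                   case_cohort = config$case_cohort,
                                   comparison_cohort =
                                     config$comparison_cohort,
                                   config = config)

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("sexdiffr")),
    counts = list(
      samples_in = n_input,
      samples_retained = nrow(pre$panel$samples),
      analytes_retained = length(panel_analytes(pre$panel)),
      analytes_pooled = sum(!pooled$excluded),
      analytes_significant = sum(pooled$significant, na.rm = TRUE)
    )
  )
  structure(list(panel = pre$panel, preprocess_report = pre$report,
                 effects = effects, pooled = pooled,
                 cluster_model = model, composites = composites,
                 truth = truth, manifest = manifest),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat("<study_run>\n")
  cts <- x$manifest$counts
  cat("  samples: ", cts$samples_retained, "/", cts$samples_in,
      " retained after matching\n", sep = "")
  cat("  analytes: ", cts$analytes_retained, " retained, ",
      cts$analytes_pooled, " pooled, ", cts$analytes_significant,
      " significant\n", sep = "")
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Prints the counts of significantly sex-different analytes by
#' direction, each cluster's pooled composite difference with its
#' confidence interval, and the sex-by-condition interaction q-values
#' (naming clusters below the significance level).
#'
#' @param run A `study_run` from [run_pipeline()].
#' @return Invisibly, a list with `counts`, `composites`, and
#'   `interactions` tibbles.
#' @export
report_summary <- function(run) {
  pooled <- run$pooled
  alpha <- attr(pooled, "alpha") %||% 0.05
  sig <- pooled %>% filter(.data$significant)
  counts <- tibble(
    direction = c("male_higher", "female_higher"),
    n = c(sum(sig$direction == "male_higher"),
          sum(sig$direction == "female_higher"))
  )
  cat("Significant analytes (q < ", alpha, "): ", nrow(sig), "\n",
      sep = "")
  cat("  male_higher: ", counts$n[1], "\n", sep = "")
  cat("  female_higher: ", counts$n[2], "\n", sep = "")

  cl <- run$composites$clusters
  cat("Composite sex differences (male - female, pooled):\n")
  for (i in seq_len(nrow(cl))) {
    cat(sprintf("  cluster %s: %+.3f [%.3f, %.3f]\n", cl$cluster[i],
                cl$delta_pooled[i], cl$ci_low[i], cl$ci_high[i]))
  }
  cat("Sex-by-condition interaction:\n")
  for (i in seq_len(nrow(cl))) {
    flag <- if (!is.na(cl$interaction_q[i]) &&
                cl$interaction_q[i] < alpha) "  <-- significant" else ""
    cat(sprintf("  cluster %s: p = %.4g, q = %.4g%s\n", cl$cluster[i],
                cl$interaction_p[i], cl$interaction_q[i], flag))
  }
  invisible(list(counts = counts,
                 composites = cl %>%
                   select("cluster", "delta_pooled", "ci_low", "ci_high"),
                 interactions = cl %>%
                   select("cluster", "interaction_F", "interaction_p",
                          "interaction_q")))
}
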