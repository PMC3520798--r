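#' Synthetic multi-cohort study designs
#'
#' `default_design()` builds a simulation design mirroring the structure
#' of the multi-site serum study the pipeline targets: nine control
#' cohorts with per-sex sizes 20/25/7/10/13/11/81/22/7 (392 controls,
#' 196 male and 196 female), one 22/22 case cohort, and 174 analytes
#' organised into six latent clusters. Concentrations are log-normal;
#' sex effects act additively on the log scale, so each analyte's
#' marginal male-versus-female Cliff's delta has the closed form
#' `2 * pnorm(-beta / (sqrt(2) * sigma_tot)) - 1` with
#' `sigma_tot^2 = lambda^2 + sigma^2`.
#'
#' Between-cohort heterogeneity multiplies the sex effect
#' (`beta * (1 + b)`, `b ~ N(0, tau_rel^2)` per analyte and cohort),
#' matching the random-effects premise of the pooling stage. One cluster
#' carries an additional female-case shift so the sex-by-condition
#' interaction stage has a recoverable signal.
#'
#' @param scale Fraction in (0, 1] rescaling all cohort sizes (floored,
#'   minimum 2 per sex).
#' @param n_analytes Number of analytes.
#' @param k_true Number of latent analyte clusters.
#' @param frac_nonnull Fraction of analytes with a non-zero sex effect.
#' @param tau_rel Relative between-cohort SD of the sex effect.
#' @param lambda Latent-factor loading shared by analytes of a cluster;
#'   with the default residual SDs this gives a log-scale
#'   within-cluster correlation of about 0.24.
#' @param interaction_cluster Cluster index carrying the planted
#'   sex-by-condition interaction (`0` for none).
#' @param interaction_shift Female-case shift in units of `sigma_tot`
#'   (negative: female cases sit below the typical female level).
#' @param miss_rate,outlier_rate Per-cell probabilities of
#'   missing-at-random cells and of multiplicative outliers.
#' @param outlier_factor Multiplier applied to outlier cells.
#' @param gamma_sd SD of per-(analyte, cohort) baseline shifts (site and
#'   batch differences).
#' @param censor Logical; if `FALSE` the design has no detection limits
#'   (`lod = 0`, `uloq = Inf`).
#' @param seed Integer seed; fixes both the design's analyte parameters
#'   and (by default) the simulation draw.
#'
#' @return A list of class `simulation_design` with tibbles `cohorts`
#'   and `analytes` plus scalar parameters.
#' @export
default_design <- function(scale = 1,
                           n_analytes = 174,
                           k_true = 6,
                           frac_nonnull = 0.45,
                           tau_rel = 0.3,
                           lambda = 0.28,
                           interaction_cluster = 1,
                           interaction_shift = -0.8,
                           miss_rate = 0.02,
                           outlier_rate = 0.005,
                           outlier_factor = 8,
                           gamma_sd = 0.3,
                           censor = TRUE,
                           seed = 1L) {
  if (scale <= 0 || scale > 1) abort("scale must be in (0, 1]")
  per_sex <- c(20, 25, 7, 10, 13, 11, 81, 22, 7)
  n_sex <- pmax(2L, as.integer(floor(scale * per_sex)))
  cohorts <- tibble(
    cohort_id = sprintf("cohort_%d", seq_along(per_sex)),
    n_male = n_sex, n_female = n_sex,
    condition = "control"
  ) %>%
    bind_rows(tibble(cohort_id = "cohort_10",
                     n_male = pmax(2L, as.integer(floor(scale * 22))),
                     n_female = pmax(2L, as.integer(floor(scale * 22))),
                     condition = "case"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  cluster <- sort(rep_len(seq_len(k_true), n_analytes))
  mu <- runif(n_analytes, log(0.5), log(500))
  sigma <- runif(n_analytes, 0.45, 0.55)
  lam <- rep(lambda, n_analytes)
  sigma_tot <- sqrt(lam^2 + sigma^2)

  beta <- numeric(n_analytes)
  n_nn <- round(frac_nonnull * n_analytes)
  if (n_nn > 0) {
    idx <- unique(round(seq(1, n_analytes, length.out = n_nn)))
    mag <- runif(length(idx), 0.15, 0.85)
    sign <- rep(c(1, -1), length.out = length(idx))
    delta_target <- -sign * mag  # alternate female- and male-elevated
    beta[idx] <- beta_for_delta(delta_target, sigma_tot[idx])
  }

  interaction <- numeric(n_analytes)
  if (interaction_cluster > 0) {
    in_cl <- cluster == interaction_cluster
    interaction[in_cl] <- interaction_shift * sigma_tot[in_cl]
  }

  s_marg <- sqrt(sigma_tot^2 + gamma_sd^2)
  lod <- if (censor) exp(mu + qnorm(0.015) * s_marg) else rep(0, n_analytes)
  uloq <- if (censor) exp(mu + qnorm(0.995) * s_marg) else rep(Inf, n_analytes)

  analytes <- tibble(
    analyte = sprintf("analyte_%03d", seq_len(n_analytes)),
    cluster = cluster, mu = mu, sigma = sigma, lambda = lam,
    sigma_tot = sigma_tot, beta = beta, interaction = interaction,
    lod = lod, uloq = uloq
  )
  structure(list(
    cohorts = cohorts, analytes = analytes,
    tau_rel = tau_rel, gamma_sd = gamma_sd,
    miss_rate = miss_rate, outlier_rate = outlier_rate,
    outlier_factor = outlier_factor, seed = as.integer(seed)
  ), class = "simulation_design")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sex-effect size for a target Cliff's delta
#'
#' For log-normal concentrations with total log-scale SD `sigma_tot` per
#' group, a log-scale female-minus-male shift `beta` yields a marginal
#' male-versus-female Cliff's delta of
#' `2 * pnorm(-beta / (sqrt(2) * sigma_tot)) - 1`. These helpers invert
#' and evaluate that relation.
#'
#' @param delta Target Cliff's delta in (-1, 1) (positive = male-higher).
#' @param sigma_tot Total log-scale SD (`sqrt(lambda^2 + sigma^2)`).
#' @return `beta_for_delta()` returns the log-scale shift;
#'   `delta_for_beta()` the implied Cliff's delta.
#' @export
beta_for_delta <- function(delta, sigma_tot) {
  stopifnot(all(abs(delta) < 1), all(sigma_tot > 0))
  -qnorm((delta + 1) / 2) * sqrt(2) * sigma_tot
}

#' @rdname beta_for_delta
#' @param beta Log-scale female-minus-male shift.
#' @export
delta_for_beta <- function(beta, sigma_tot) {
  stopifnot(all(sigma_tot > 0))
  2 * pnorm(-beta / (sqrt(2) * sigma_tot)) - 1
}

#' Simulate a multi-cohort serum panel with ground truth
#'
#' Draws a full study from a [default_design()]-style design. For sample
#' `s` in cohort `h` (sex `g`, condition `c`) and analyte `a` in cluster
#' `kappa`, the log concentration is
#' `mu_a + gamma_{a,h} + lambda_kappa * u_{s,kappa} +
#'  beta_a * (1 + b_{a,h}) * I(g = F) + interaction_a * I(F) * I(case) +
#'  eps` with `u ~ N(0,1)` shared by all analytes of a cluster within a
#' sample, `b ~ N(0, tau_rel^2)` drawn once per (analyte, cohort), and
#' `eps ~ N(0, sigma_a^2)`. Concentrations below `lod` / above `uloq`
#' are censored to `BELOW_RANGE` / `ABOVE_RANGE`; independent
#' missing-at-random cells and multiplicative outliers are then applied.
#'
#' @param design A `simulation_design`.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A list of class `simulated_study` with elements `panel` (an
#'   [analyte_panel]) and `truth` (a list with per-analyte tibble
#'   `analytes` — including the closed-form `delta_true` — and the
#'   per-(analyte, cohort) `cohort_multipliers`).
#' @export
simulate_study <- function(design, seed = design$seed) {
  if (!inherits(design, "simulation_design")) {
    abort("design must be a simulation_design (see default_design())")
  }
  an <- design$analytes
  co <- design$cohorts
  if (any(an$sigma <= 0) || any(an$lambda < 0)) abort("invalid design: SDs")
  if (any(an$sigma_tot <= 0)) abort("invalid design: degenerate sigma_tot")
  if (any(an$lod >= an$uloq)) abort("invalid design: lod >= uloq")
  if (any(co$n_male < 2 | co$n_female < 2)) {
    abort("invalid design: cohorts need >= 2 samples per sex")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_a <- nrow(an)
  k_true <- max(an$cluster)

  samples <- purrr::pmap_dfr(co, function(cohort_id, n_male, n_female,
                                          condition) {
    n <- n_male + n_female
    tibble(
      sample_id = sprintf("%s_s%03d", cohort_id, seq_len(n)),
      cohort_id = cohort_id,
      sex = rep(c("M", "F"), c(n_male, n_female)),
      condition = condition
    )
  })
  n_s <- nrow(samples)
  # nuisance covariates (no confounding): drawn independently of sex
  samples$age <- round(pmin(65, pmax(18, rnorm(n_s, 32, 9))))
  samples$bmi <- round(rnorm(n_s, 24, 3), 1)
  samples$waist_circumference <- round(rnorm(n_s, 97, 8))
  samples$smoking <- sample(c("Y", "N"), n_s, TRUE, prob = c(0.2, 0.8))
  samples$cannabis <- sample(c("Y", "N", NA), n_s, TRUE,
                             prob = c(0.05, 0.85, 0.10))

  b <- matrix(rnorm(n_a * nrow(co), 0, design$tau_rel), n_a, nrow(co),
              dimnames = list(an$analyte, co$cohort_id))
  gamma <- matrix(rnorm(n_a * nrow(co), 0, design$gamma_sd), n_a, nrow(co),
                  dimnames = list(an$analyte, co$cohort_id))

  u <- matrix(rnorm(n_s * k_true), n_s, k_true)
  eps <- matrix(rnorm(n_s * n_a), n_s, n_a) *
    matrix(an$sigma, n_s, n_a, byrow = TRUE)

  h <- match(samples$cohort_id, co$cohort_id)
  is_f <- samples$sex == "F"
  is_case <- samples$condition == "case"

  logx <- matrix(an$mu, n_s, n_a, byrow = TRUE) +
    t(gamma)[h, , drop = FALSE] +
    u[, an$cluster, drop = FALSE] *
      matrix(an$lambda, n_s, n_a, byrow = TRUE) +
    (is_f * (1 + t(b)[h, , drop = FALSE])) *
      matrix(an$beta, n_s, n_a, byrow = TRUE) +
    outer(is_f & is_case, an$interaction) +
    eps
  x <- exp(logx)

  status <- matrix("OK", n_s, n_a)
  status[x < matrix(an$lod, n_s, n_a, byrow = TRUE)] <- "BELOW_RANGE"
  status[x > matrix(an$uloq, n_s, n_a, byrow = TRUE)] <- "ABOVE_RANGE"
  miss <- matrix(runif(n_s * n_a) < design$miss_rate, n_s, n_a)
  status[miss] <- "MISSING"
  outl <- matrix(runif(n_s * n_a) < design$outlier_rate, n_s, n_a) &
    status == "OK"
  x[outl] <- x[outl] * design$outlier_factor
  x[status != "OK"] <- NA_real_

  measurements <- tibble(
    sample_id = rep(samples$sample_id, times = n_a),
    analyte = rep(an$analyte, each = n_s),
    value = as.vector(x),
    status = as.vector(status)
  )

  truth <- list(
    analytes = an %>%
      mutate(delta_true = delta_for_beta(.data$beta, .data$sigma_tot),
             has_interaction = .data$interaction != 0) %>%
      select("analyte", "cluster", "beta", "sigma_tot", "delta_true",
             "interaction", "has_interaction"),
    cohort_multipliers = tidyr::expand_grid(
      analyte = an$analyte, cohort_id = co$cohort_id) %>%
      mutate(multiplier = 1 + b[cbind(match(.data$analyte, an$analyte),
                                      match(.data$cohort_id, co$cohort_id))])
  )

  structure(list(panel = analyte_panel(samples, measurements),
                 truth = truth, design = design, seed = as.integer(seed)),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> seed", x$seed, "\n")
  print(x$panel)
  invisible(x)
}
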