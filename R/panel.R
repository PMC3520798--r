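#' Serum analyte panels
#'
#' An `analyte_panel` holds a multi-cohort serum immunoassay panel: one row
#' of sample metadata per participant (cohort, sex, condition, matching
#' covariates) plus a long table of per-sample, per-analyte measurements.
#' Every (sample, analyte) cell carries exactly one status flag:
#'
#' * `"OK"` — a usable numeric concentration,
#' * `"MISSING"` — no measurement,
#' * `"BELOW_RANGE"` / `"ABOVE_RANGE"` — censored outside the assay's
#'   linear range (no numeric value until [replace_out_of_range()] runs),
#' * `"OUTLIER_REMOVED"` — excluded by [remove_outliers()].
#'
#' @param samples A data frame with columns `sample_id`, `cohort_id`,
#'   `sex` (`"M"`/`"F"`), `condition` (`"control"`/`"case"`) and any
#'   covariate columns (e.g. `age`, `bmi`, `waist_circumference`,
#'   `smoking`, `cannabis`).
#' @param measurements A data frame with columns `sample_id`, `analyte`,
#'   `value` (numeric, `NA` unless status is `"OK"`), `status`.
#'
#' @return An object of class `analyte_panel`: a list with tibbles
#'   `samples` and `measurements`.
#' @export
analyte_panel <- function(samples, measurements) {
  samples <- as_tibble(samples)
  measurements <- as_tibble(measurements)
  validate_panel(new_panel(samples, measurements))
}

new_panel <- function(samples, measurements) {
  structure(list(samples = samples, measurements = measurements),
            class = "analyte_panel")
}

panel_statuses <- c("OK", "MISSING", "BELOW_RANGE", "ABOVE_RANGE",
                    "OUTLIER_REMOVED")

validate_panel <- function(panel) {
  s <- panel$samples
  m <- panel$measurements
  need <- setdiff(c("sample_id", "cohort_id", "sex", "condition"), names(s))
  if (length(need)) {
    abort(paste0("panel samples lack column(s): ", toString(need)))
  }
  if (anyDuplicated(s$sample_id)) {
    dup <- s$sample_id[duplicated(s$sample_id)][1]
    abort(paste0("duplicate sample_id: ", dup))
  }
  bad_sex <- !s$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(paste0("sample ", s$sample_id[bad_sex][1],
                 " has unknown sex code '", s$sex[bad_sex][1], "'"))
  }
  bad_cond <- !s$condition %in% c("control", "case")
  if (any(bad_cond)) {
    abort(paste0("sample ", s$sample_id[bad_cond][1],
                 " has unknown condition code '", s$condition[bad_cond][1], "'"))
  }
  need_m <- setdiff(c("sample_id", "analyte", "value", "status"), names(m))
  if (length(need_m)) {
    abort(paste0("panel measurements lack column(s): ", toString(need_m)))
  }
  bad_status <- !m$status %in% panel_statuses
  if (any(bad_status)) {
    abort(paste0("unknown measurement status '", m$status[bad_status][1], "'"))
  }
  if (any(m$status == "OK" & !is.finite(m$value))) {
    abort("measurement with status OK lacks a finite value")
  }
  if (any(m$status != "OK" & !is.na(m$value))) {
    abort("measurement with non-OK status carries a value")
  }
  orphan <- setdiff(m$sample_id, s$sample_id)
  if (length(orphan)) {
    abort(paste0("measurements reference unknown sample_id: ", orphan[1]))
  }
  panel
}

#' @export
print.analyte_panel <- function(x, ...) {
  n_s <- nrow(x$samples)
  n_a <- length(unique(x$measurements$analyte))
  coh <- x$samples %>%
    count(.data$cohort_id, .data$condition) %>%
    arrange(.data$cohort_id)
  cat("<analyte_panel> ", n_s, " samples, ", n_a, " analytes, ",
      nrow(coh), " cohorts\n", sep = "")
  st <- table(x$measurements$status)
  cat("  cells:", paste(names(st), as.integer(st), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Panel accessors
#'
#' `panel_analytes()` lists the analytes present in a panel;
#' `panel_cohorts()` summarises cohorts (size and male/female counts).
#'
#' @param panel An [analyte_panel].
#' @return A character vector (`panel_analytes`) or a tibble
#'   (`panel_cohorts`).
#' @export
panel_analytes <- function(panel) {
  sort(unique(panel$measurements$analyte))
}

#' @rdname panel_analytes
#' @export
panel_cohorts <- function(panel) {
  panel$samples %>%
    group_by(.data$cohort_id, .data$condition) %>%
    summarise(n = n(),
              n_male = sum(.data$sex == "M"),
              n_female = sum(.data$sex == "F"),
              .groups = "drop") %>%
    arrange(.data$cohort_id)
}

## Wide numeric matrix (samples x analytes) of usable values; non-OK -> NA.
panel_matrix <- function(panel, cohort = NULL, samples = NULL) {
  keep <- panel$samples
  if (!is.null(cohort)) keep <- filter(keep, .data$cohort_id %in% !!cohort)
  if (!is.null(samples)) keep <- filter(keep, .data$sample_id %in% !!samples)
  m <- panel$measurements %>% filter(.data$sample_id %in% keep$sample_id)
  analytes <- sort(unique(panel$measurements$analyte))
  out <- matrix(NA_real_, nrow = nrow(keep), ncol = length(analytes),
                dimnames = list(keep$sample_id, analytes))
  ok <- m$status == "OK"
  out[cbind(match(m$sample_id[ok], keep$sample_id),
            match(m$analyte[ok], analytes))] <- m$value[ok]
  out
}

default_dialect <- function() {
  list(below = "<LOW>", above = ">HIGH>", missing = c("", "NA"),
       outlier = "<OUTLIER>")
}

reserved_cols <- c("sample_id", "cohort_id", "sex", "condition")
default_covariates <- c("age", "bmi", "waist_circumference", "smoking",
                        "cannabis")

#' Read and write analyte panels
#'
#' Panels are exchanged as wide delimited text (one column per analyte,
#' `.csv` comma / `.tsv` tab, auto-detected from the extension) with a
#' mandatory header. Cells outside the assay range are encoded with
#' sentinel tokens; the dialect is configurable because vendors differ.
#'
#' @param path File to read or write.
#' @param dialect Named list with entries `below`, `above`, `missing`
#'   (character vectors of sentinel tokens) and `outlier`; see
#'   `default_dialect` entries `"<LOW>"`, `">HIGH>"`, `""`/`"NA"`,
#'   `"<OUTLIER>"`.
#' @param covariate_cols Column names treated as sample covariates rather
#'   than analytes.
#' @return `read_panel()` returns an [analyte_panel]; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path, dialect = default_dialect(),
                       covariate_cols = default_covariates) {
  if (!file.exists(path)) abort(paste0("no such panel file: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(),
    progress = FALSE)
  need <- setdiff(reserved_cols, names(raw))
  if (length(need)) {
    abort(paste0("panel file lacks required column(s): ", toString(need)))
  }
  cov_present <- intersect(covariate_cols, names(raw))
  analyte_cols <- setdiff(names(raw), c(reserved_cols, cov_present))
  if (!length(analyte_cols)) abort("panel file contains no analyte columns")

  samples <- raw %>% select(all_of(c(reserved_cols, cov_present)))
  for (cc in cov_present) {
    v <- samples[[cc]]
    v[v %in% dialect$missing] <- NA
    suppressWarnings(num <- as.numeric(v))
    samples[[cc]] <- if (all(is.na(num) == is.na(v))) num else v
  }

  long <- raw %>%
    select(all_of(c("sample_id", analyte_cols))) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "analyte",
                        values_to = "token")
  tok <- long$token
  status <- rep("OK", length(tok))
  status[tok %in% dialect$missing] <- "MISSING"
  status[tok %in% dialect$below] <- "BELOW_RANGE"
  status[tok %in% dialect$above] <- "ABOVE_RANGE"
  status[tok %in% dialect$outlier] <- "OUTLIER_REMOVED"
  value <- rep(NA_real_, length(tok))
  is_ok <- status == "OK"
  suppressWarnings(value[is_ok] <- as.numeric(tok[is_ok]))
  bad <- is_ok & is.na(value)
  if (any(bad)) {
    abort(paste0("non-numeric, non-sentinel cell for sample ",
                 long$sample_id[bad][1], ", analyte ", long$analyte[bad][1],
                 ": '", tok[bad][1], "'"))
  }
  long <- long %>% mutate(value = value, status = status) %>%
    select(-"token")
  analyte_panel(samples, long)
}

#' @param panel An [analyte_panel] to serialize.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path, dialect = default_dialect()) {
  wide <- panel$measurements %>%
    mutate(token = case_when(
      .data$status == "OK" ~ format(.data$value, digits = 15, trim = TRUE,
                                    scientific = FALSE),
      .data$status == "MISSING" ~ dialect$missing[1],
      .data$status == "BELOW_RANGE" ~ dialect$below[1],
      .data$status == "ABOVE_RANGE" ~ dialect$above[1],
      .data$status == "OUTLIER_REMOVED" ~ dialect$outlier[1]
    )) %>%
    select("sample_id", "analyte", "token") %>%
    tidyr::pivot_wider(names_from = "analyte", values_from = "token")
  out <- panel$samples %>%
    mutate(across(everything(), as.character)) %>%
    left_join(wide, by = "sample_id")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Serialize pooled effect tables
#'
#' Writes the per-analyte pooled results of [run_meta()] as tab-delimited
#' text, ordered by q-value and then analyte name, and reads them back.
#' Numeric fields round-trip to at least 12 significant digits.
#'
#' @param effects A non-empty tibble of pooled effects (from [run_meta()]).
#' @param path Output file path.
#' @return `write_effect_table()` returns `path` invisibly;
#'   `read_effect_table()` returns a tibble.
#' @export
write_effect_table <- function(effects, path) {
  if (is.null(effects) || !nrow(effects)) {
    abort("effect table is empty; nothing to write")
  }
  effects <- effects %>% arrange(.data$q, .data$analyte)
  readr::write_tsv(effects, path, na = "NA")
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
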