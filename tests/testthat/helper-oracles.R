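# Independent oracles used across the suite. These deliberately use the
# naive O(mn) / brute-force definitions rather than the package's
# algorithms.

# Pairwise sign count over the full dominance matrix.
brute_delta <- function(x, y) {
  s <- outer(x, y, function(a, b) sign(a - b))
  sum(s) / (length(x) * length(y))
}

# Cliff's consistent variance evaluated literally on the dominance
# matrix, with the same degenerate-case floors the package documents.
brute_delta_variance <- function(x, y) {
  m <- length(x); n <- length(y)
  s <- outer(x, y, function(a, b) sign(a - b))
  d <- sum(s) / (m * n)
  di <- rowMeans(s); dj <- colMeans(s)
  v <- (n^2 * sum((di - d)^2) + m^2 * sum((dj - d)^2) -
          sum((s - d)^2)) / (m * n * (m - 1) * (n - 1))
  if (v <= 0) {
    v <- if (abs(d) >= 1) {
      ds <- (m * n - 1) / (m * n)
      (1 - ds^2) / (m * n - 1)
    } else {
      (1 - d^2) / (m * n - 1)
    }
  }
  v
}

# Literal step-up evaluation of the Benjamini-Hochberg definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, p[ord[j]] * m / j), 0)
    q_sorted[i] <- min(cand)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small wide-format panel builder: `values` is a named list of numeric
# vectors (NA = missing), `status` an optional matching list of status
# strings overriding the default OK/MISSING mapping.
toy_panel <- function(values, sex, cohort_id = "c1", condition = "control",
                      status = NULL, covs = NULL) {
  n <- length(sex)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    cohort_id = rep_len(cohort_id, n),
    sex = sex,
    condition = rep_len(condition, n)
  )
  if (!is.null(covs)) samples <- dplyr::bind_cols(samples, covs)
  meas <- lapply(names(values), function(a) {
    v <- values[[a]]
    st <- if (!is.null(status) && !is.null(status[[a]])) status[[a]] else
      ifelse(is.na(v), "MISSING", "OK")
    tibble::tibble(sample_id = samples$sample_id, analyte = a,
                   value = ifelse(st == "OK", v, NA_real_), status = st)
  })
  sexdiffr::analyte_panel(samples, dplyr::bind_rows(meas))
}

# Minimal cluster model wrapping a fixed assignment (no k-means fit).
fixed_cluster_model <- function(analytes, cluster = 1L) {
  structure(list(assignment = tibble::tibble(analyte = analytes,
                                             cluster = cluster)),
            class = "cluster_model")
}

# Adjusted Rand index between two labelings (closed-form from the
# contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
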