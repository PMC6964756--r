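#' Signed percent difference against a reference
#'
#' `100 * (value - reference) / reference`, the per-target agreement metric
#' between a secondary dose calculation and the treatment planning system.
#' The reference engine must always be stated explicitly; swapping the
#' arguments is not a sign flip.
#'
#' @param value numeric vector (e.g. secondary doses, Gy).
#' @param reference numeric vector (e.g. TPS doses, Gy); no zeros.
#' @return Numeric vector of signed percent differences.
#' @examples
#' percent_difference(3.91, 4.0) # -2.25
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) abort("`reference` must be non-zero")
  100 * (value - reference) / reference
}

new_htest <- function(method, statistic, p_value, n, exact, degenerate = FALSE,
                      extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value,
           n = n, exact = exact, degenerate = degenerate), extra),
    class = "gk_htest"
  )
}

#' @export
print.gk_htest <- function(x, ...) {
  cat(sprintf("<gk_htest> %s: statistic = %.6g, p = %.4g (%s%s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "asymptotic",
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' @export
tidy.gk_htest <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p_value,
         n = sum(x$n), exact = x$exact, degenerate = x$degenerate)
}

# two-sided p for a statistic symmetric about mu: P(|T - mu| >= |t - mu|)
sym_two_sided <- function(values, mu, observed) {
  mean(abs(values - mu) >= abs(observed - mu) - 1e-9)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided test on `a - b`. Zero differences are dropped and
#' counted (`n_zero`). For `n <= exact_max` remaining pairs the p-value is
#' computed by exhaustive enumeration of all `2^n` sign assignments of the
#' tied-averaged ranks (valid under ties); otherwise by the normal
#' approximation with tie-corrected variance.
#'
#' @param a,b equal-length numeric vectors.
#' @param exact_max exact-enumeration crossover (default 15).
#' @return A `gk_htest` with statistic `W+` (sum of positive ranks), fields
#'   `n_zero`, and `degenerate = TRUE` when all differences are zero.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 15) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_htest("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                     n = 0L, exact = TRUE, degenerate = TRUE,
                     extra = list(n_zero = n_zero)))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # distribution of W+ over all sign assignments of the observed ranks
    ids <- 0:(2^n - 1)
    signs <- (outer(ids, 2^(0:(n - 1)), function(i, b) i %/% b) %% 2) == 1
    Wall <- as.numeric(signs %*% r)
    p <- sym_two_sided(Wall, mu, W)
    exact <- TRUE
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_htest("Wilcoxon signed-rank", statistic = W, p_value = min(1, p),
            n = n, exact = exact, extra = list(n_zero = n_zero))
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum test. The statistic is `U_a`, the number of (a, b)
#' pairs with `a > b` counting ties as 1/2. The p-value is exact (full
#' enumeration of group labelings, valid under ties) when the smaller group
#' has at most `exact_max` members and the labeling count is tractable;
#' otherwise the tie-corrected normal approximation is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max exact-enumeration crossover on `min(n_a, n_b)`
#'   (default 8).
#' @return A `gk_htest` with statistic `U_a`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) abort("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (min(na, nb) <= exact_max && choose(n, min(na, nb)) <= 2e5) {
    k <- min(na, nb)
    combos <- utils::combn(n, k)
    Rk <- colSums(matrix(r[combos], nrow = k))
    Uk <- Rk - k * (k + 1) / 2
    # statistic for the smaller group; symmetric null around na*nb/2
    U_obs <- if (na <= nb) U else na * nb - U
    p <- sym_two_sided(Uk, mu, U_obs)
    exact <- TRUE
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_htest("Mann-Whitney U", statistic = U, p_value = min(1, p),
            n = c(n_a = na, n_b = nb), exact = exact)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a two-sided p-value from the
#' normal approximation with the full tie-corrected variance of the
#' concordance score S.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return A `gk_htest` with statistic tau-b and field `S`; a constant
#'   vector yields `degenerate = TRUE` with `NA` tau.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) abort("`x` and `y` must have equal length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(new_htest("Kendall tau-b", statistic = NA_real_, p_value = NA_real_,
                     n = n, exact = FALSE, degenerate = TRUE))
  }
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  S <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  p <- 2 * stats::pnorm(-abs(z))
  new_htest("Kendall tau-b", statistic = tau, p_value = p, n = n,
            exact = FALSE, extra = list(S = S))
}

#' Build cohort records from paired dose calculations
#'
#' @param target_id identifier vector.
#' @param reference_dose,secondary_dose paired doses, Gy.
#' @param average_depth_cm per-target average calculation depth, cm.
#' @param gamma_deg per-target gamma angle, degrees.
#' @return A tibble of cohort records with `percent_diff`,
#'   `abs_percent_diff` and `gamma_category` ("standard" at 90 degrees,
#'   "nonstandard" otherwise).
#' @export
cohort_records <- function(target_id, reference_dose, secondary_dose,
                           average_depth_cm = NA_real_, gamma_deg = 90) {
  pd <- percent_difference(secondary_dose, reference_dose)
  tibble(
    target_id = target_id,
    reference_dose = reference_dose, secondary_dose = secondary_dose,
    percent_diff = pd, abs_percent_diff = abs(pd),
    average_depth_cm = average_depth_cm, gamma_deg = gamma_deg,
    gamma_category = ifelse(gamma_deg == 90, "standard", "nonstandard")
  )
}

#' Cohort evaluation of secondary-vs-reference dose agreement
#'
#' Runs the full agreement audit over a cohort of paired calculations:
#' summary statistics of the absolute percent difference, the count
#' exceeding the clinical tolerance (default 5%), a Wilcoxon signed-rank
#' test of this engine's absolute differences against a comparator engine's
#' (when given), a Mann-Whitney U test of standard vs nonstandard gamma
#' categories, and a Kendall tau-b correlation of absolute percent
#' difference with average calculation depth. Statistics whose covariates
#' are missing or degenerate are skipped with a warning.
#'
#' @param records a cohort tibble as built by [cohort_records()] or
#'   [simulate_cohort()] (columns `percent_diff` or
#'   `reference_dose`/`secondary_dose`, optionally `average_depth_cm`,
#'   `gamma_deg`).
#' @param comparator optional second engine's cohort tibble, paired row-wise
#'   by target.
#' @param tolerance clinical tolerance on `abs_percent_diff`, percent
#'   (default 5).
#' @return An object of class `gk_evaluation`; see `tidy()`, `glance()`,
#'   [autoplot()].
#' @export
cohort_evaluation <- function(records, comparator = NULL, tolerance = 5) {
  records <- as_tibble(records)
  if (nrow(records) < 2L) abort("at least 2 cohort records are required")
  if (all(c("secondary_dose", "reference_dose") %in% names(records))) {
    # doses are authoritative; derived columns are recomputed
    records$percent_diff <- percent_difference(records$secondary_dose,
                                               records$reference_dose)
  } else if (!"percent_diff" %in% names(records)) {
    abort("records need `percent_diff` or `secondary_dose` + `reference_dose`")
  }
  records$abs_percent_diff <- abs(records$percent_diff)
  a <- records$abs_percent_diff

  tests <- list()
  if (!is.null(comparator)) {
    comparator <- as_tibble(comparator)
    if (all(c("secondary_dose", "reference_dose") %in% names(comparator))) {
      comparator$percent_diff <- percent_difference(comparator$secondary_dose,
                                                    comparator$reference_dose)
    }
    if (nrow(comparator) != nrow(records)) {
      abort("`comparator` must have one record per target, paired with `records`")
    }
    tests$engines_wsrt <- wilcoxon_signed_rank(a, abs(comparator$percent_diff))
  }
  gc_ <- records$gamma_category %||%
    ifelse(records$gamma_deg %||% 90 == 90, "standard", "nonstandard")
  if (length(unique(gc_)) == 2L) {
    tests$gamma_mwu <- mann_whitney_u(a[gc_ == "nonstandard"], a[gc_ == "standard"])
  } else {
    warn("single gamma category in cohort; gamma-stratified test skipped")
  }
  dep <- records$average_depth_cm
  if (!is.null(dep) && sum(!is.na(dep)) >= 3L) {
    ok <- !is.na(dep)
    tests$depth_kendall <- kendall_tau(a[ok], dep[ok])
  } else {
    warn("average calculation depth missing; depth correlation skipped")
  }

  structure(
    list(
      records = records, tolerance = tolerance,
      n = nrow(records),
      summary = tibble(
        n = nrow(records),
        median_abs = stats::median(a), mean_abs = mean(a),
        min_abs = min(a), max_abs = max(a),
        n_violations = sum(a > tolerance)
      ),
      tests = tests
    ),
    class = "gk_evaluation"
  )
}

#' @export
print.gk_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<gk_evaluation> n = %d targets\n",
           "  |%%diff|: median %.3g, mean %.3g, range %.3g-%.3g\n",
           "  violations of %g%% tolerance: %d\n"),
    s$n, s$median_abs, s$mean_abs, s$min_abs, s$max_abs,
    x$tolerance, s$n_violations
  ))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %s: statistic %.4g, p = %.4g\n", t$method, t$statistic, t$p_value))
  }
  invisible(x)
}

#' @export
tidy.gk_evaluation <- function(x, ...) {
  purrr::imap_dfr(x$tests, function(t, nm) {
    mutate(tidy(t), term = nm, .before = 1)
  })
}

#' @export
glance.gk_evaluation <- function(x, ...) {
  out <- x$summary
  out$tolerance <- x$tolerance
  if (!is.null(x$tests$depth_kendall)) {
    out$depth_tau <- x$tests$depth_kendall$statistic
    out$depth_tau_p <- x$tests$depth_kendall$p_value
  }
  if (!is.null(x$tests$gamma_mwu)) out$gamma_p <- x$tests$gamma_mwu$p_value
  if (!is.null(x$tests$engines_wsrt)) out$engines_p <- x$tests$engines_wsrt$p_value
  out
}

#' @export
autoplot.gk_evaluation <- function(object, ...) {
  d <- object$records
  d$gamma_category <- d$gamma_category %||% "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma_category,
                                  y = .data$abs_percent_diff)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$tolerance, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "|percent difference| from reference (%)") +
    ggplot2::theme_minimal()
}

#' Write / read cohort record CSVs
#'
#' @param records a cohort tibble.
#' @param path CSV path.
#' @return `read_cohort()` returns the tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
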