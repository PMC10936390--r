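#' Per-trial gait summaries: mean and coefficient of variation
#'
#' Pools strides over a trial and returns, per metric, the mean and the
#' coefficient of variation CV = 100 * sample SD / mean (sample SD uses the
#' n - 1 denominator). Stride-to-stride CV is the standard gait-variability
#' measure.
#'
#' @param strides Stride table (e.g. from [temporal_parameters()] +
#'   [spatial_parameters()]); any columns named in `metrics` are summarised.
#' @param cycles Optional per-cycle margin table from
#'   [summarize_mos_cycles()]; its `mos_ap`, `mos_ml_pos`, `mos_ml_neg`
#'   columns are summarised alongside.
#' @param metrics Character vector of stride columns to summarise.
#' @return Tibble with columns `metric`, `n`, `mean`, `cv` (percent).
#' @export
summarize_trial <- function(strides,
                            cycles = NULL,
                            metrics = c("st", "swing", "swp", "sl", "sv", "sw")) {
  pool <- strides[intersect(metrics, names(strides))]
  if (!is.null(cycles)) {
    pool <- c(as.list(pool),
              as.list(cycles[intersect(c("mos_ap", "mos_ml_pos", "mos_ml_neg"),
                                       names(cycles))]))
  }
  pool <- as.list(pool)
  out <- purrr::imap_dfr(pool, function(v, nm) {
    v <- v[is.finite(v)]
    if (length(v) < 2) {
      abort(sprintf("metric `%s` has fewer than 2 strides; cannot summarise.", nm),
            class = "gaitmos_input_error")
    }
    m <- mean(v)
    tibble::tibble(metric = nm, n = length(v), mean = m,
                   cv = if (m == 0) NA_real_ else 100 * sd(v) / abs(m))
  })
  out
}

#' Dual-task contrasts
#'
#' Per-metric difference (D - N) and ratio (D / N) between the dual-task
#' and normal walking summaries. Ratios with a near-zero normal-walking
#' denominator are flagged undefined (`NA` with `ratio_defined = FALSE`).
#'
#' @param metrics_n,metrics_d Summary tibbles from [summarize_trial()] for
#'   the normal (N) and dual-task (D) trials; metric sets must match.
#' @param tol Denominator magnitude below which a ratio is undefined.
#' @return Tibble: `metric`, `mean_N`, `mean_D`, `mean_diff`, `mean_ratio`,
#'   `cv_N`, `cv_D`, `cv_diff`, `cv_ratio`, `ratio_defined`.
#' @export
dual_task_contrasts <- function(metrics_n, metrics_d, tol = 1e-9) {
  check_columns(metrics_n, c("metric", "mean", "cv"), "metrics_n")
  check_columns(metrics_d, c("metric", "mean", "cv"), "metrics_d")
  if (!setequal(metrics_n$metric, metrics_d$metric)) {
    abort("metric sets of the N and D trials do not match.",
          class = "gaitmos_input_error")
  }
  j <- dplyr::inner_join(metrics_n, metrics_d, by = "metric",
                         suffix = c("_N", "_D"))
  safe_ratio <- function(num, den) ifelse(abs(den) < tol, NA_real_, num / den)
  j |>
    dplyr::transmute(
      .data$metric,
      mean_N = .data$mean_N, mean_D = .data$mean_D,
      mean_diff = .data$mean_D - .data$mean_N,
      mean_ratio = safe_ratio(.data$mean_D, .data$mean_N),
      cv_N = .data$cv_N, cv_D = .data$cv_D,
      cv_diff = .data$cv_D - .data$cv_N,
      cv_ratio = safe_ratio(.data$cv_D, .data$cv_N),
      ratio_defined = abs(.data$mean_N) >= tol)
}

#' Hierarchical linear regression with delta R-squared
#'
#' Fits an ordinary-least-squares base model (default predictors: age and
#' gender) and a complete model adding one predictor (SPPB or MoCA), and
#' reports both coefficients of determination, their difference
#' `delta_r2 = r2_complete - r2_base`, unstandardised coefficients with 95%
#' t-based confidence intervals, standardised coefficients (obtained by
#' z-scoring outcome and predictors), and per-coefficient p-values.
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param base Character vector of base-model predictors.
#' @param added Character vector (usually length 1) of predictors added in
#'   the complete model.
#' @param conf_level Confidence level for the coefficient intervals.
#' @return A `hier_reg` object; see [tidy.hier_reg()] and
#'   [glance.hier_reg()].
#' @export
hierarchical_regression <- function(data, outcome, base = c("age", "gender"),
                                    added = "sppb", conf_level = 0.95) {
  vars <- c(outcome, base, added)
  check_columns(data, vars, "data")
  df <- tibble::as_tibble(data)[vars]
  df <- df[complete.cases(df), ]
  n <- nrow(df)
  if (n <= length(base) + length(added) + 1) {
    abort("too few complete observations for the complete model.",
          class = "gaitmos_input_error")
  }
  X <- as.matrix(df[c(base, added)])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1), qrX$pivot[seq_len(qrX$rank)])
    abort(sprintf("rank-deficient design: collinear column(s) %s.",
                  paste(c("(intercept)", colnames(X))[drop_idx], collapse = ", ")),
          class = "gaitmos_input_error")
  }
  f_base <- stats::as.formula(
    paste(outcome, "~", paste(base, collapse = " + ")))
  f_full <- stats::as.formula(
    paste(outcome, "~", paste(c(base, added), collapse = " + ")))
  m_base <- lm(f_base, data = df)
  m_full <- lm(f_full, data = df)
  # summary()/confint() warn on zero-residual fits; that case is legitimate
  # here and reported through `perfect_fit`
  r2 <- function(m) suppressWarnings(summary(m)$r.squared)
  sm <- suppressWarnings(summary(m_full))
  perfect <- sm$sigma < 1e-10
  ci <- suppressWarnings(stats::confint(m_full, level = conf_level))
  zdf <- as.data.frame(lapply(df, function(v) {
    s <- sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  }))
  m_std <- suppressWarnings(lm(f_full, data = zdf))
  coefs <- tibble::tibble(
    term = names(coef(m_full)),
    b = as.numeric(coef(m_full)),
    ci_low = ci[, 1], ci_high = ci[, 2],
    beta = as.numeric(coef(m_std)),
    p = sm$coefficients[, "Pr(>|t|)"])
  structure(list(
    outcome = outcome, base = base, added = added, n = n,
    r2_base = r2(m_base), r2_complete = r2(m_full),
    delta_r2 = r2(m_full) - r2(m_base),
    coefficients = coefs, perfect_fit = perfect,
    conf_level = conf_level, model_base = m_base, model_complete = m_full),
    class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("<hier_reg> %s ~ %s (+ %s), n = %d\n", x$outcome,
              paste(x$base, collapse = " + "),
              paste(x$added, collapse = " + "), x$n))
  cat(sprintf("  R2 base = %.4f, R2 complete = %.4f, delta R2 = %.4f%s\n",
              x$r2_base, x$r2_complete, x$delta_r2,
              if (x$perfect_fit) " (perfect fit)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a hierarchical regression
#'
#' @param x A `hier_reg` object.
#' @param ... Unused.
#' @return Tibble with one row per complete-model term: `term`, `b`,
#'   `ci_low`, `ci_high`, `beta`, `p`.
#' @export
tidy.hier_reg <- function(x, ...) x$coefficients

#' One-row summary of a hierarchical regression
#'
#' @param x A `hier_reg` object.
#' @param ... Unused.
#' @return Tibble: `outcome`, `n`, `r2_base`, `r2_complete`, `delta_r2`,
#'   `perfect_fit`.
#' @export
glance.hier_reg <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n, r2_base = x$r2_base,
                 r2_complete = x$r2_complete, delta_r2 = x$delta_r2,
                 perfect_fit = x$perfect_fit)
}

#' Run the hierarchical regressions over many outcomes
#'
#' Convenience wrapper fitting one [hierarchical_regression()] per
#' (outcome, added predictor) pair and returning a tidy results table.
#'
#' @param data Cohort data frame.
#' @param outcomes Character vector of outcome columns.
#' @param added_predictors Character vector, e.g. `c("sppb", "moca")`.
#' @param base Base-model predictors.
#' @param adjust_p Apply Benjamini-Hochberg correction across the added
#'   predictors' p-values.
#' @return Tibble with one row per model: outcome, predictor, b, CI, beta,
#'   p (optionally BH-adjusted as `p_adj`), r2_base, r2_complete, delta_r2.
#' @export
regression_table <- function(data, outcomes, added_predictors = c("sppb", "moca"),
                             base = c("age", "gender"), adjust_p = FALSE) {
  grid <- tidyr::expand_grid(outcome = outcomes, added = added_predictors)
  out <- purrr::pmap_dfr(grid, function(outcome, added) {
    fit <- hierarchical_regression(data, outcome, base = base, added = added)
    row <- fit$coefficients[fit$coefficients$term == added, ]
    tibble::tibble(outcome = outcome, predictor = added, n = fit$n,
                   b = row$b, ci_low = row$ci_low, ci_high = row$ci_high,
                   beta = row$beta, p = row$p, r2_base = fit$r2_base,
                   r2_complete = fit$r2_complete, delta_r2 = fit$delta_r2)
  })
  if (adjust_p) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Smallest detectable effect size for a multiple regression F-test
#'
#' Solves for the smallest Cohen's f-squared at which the omnibus F-test of
#' a `u`-predictor linear model (numerator df `u`, denominator df
#' `n - u - 1`) attains the target power at level `alpha`, by root-finding
#' on the strictly increasing power function of the noncentral F
#' distribution.
#'
#' The noncentrality parameter is `lambda = f2 * m` where the multiplier
#' `m` depends on the convention: `"total_df"` (default) uses
#' `m = u + v = n - 1`; `"n"` uses `m = n` (the convention of common power
#' software). The default reproduces the published sensitivity analysis for
#' this study design (n = 22, three predictors: f2 = 0.65); conventions are
#' discussed in the methods vignette.
#'
#' @param n Sample size.
#' @param alpha Significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param u Number of predictors (numerator df), >= 1.
#' @param ncp Noncentrality convention, `"total_df"` or `"n"`.
#' @return Cohen's f-squared (single number).
#' @examples
#' detectable_effect_size(n = 22, alpha = 0.05, power = 0.8, u = 3)
#' @export
detectable_effect_size <- function(n, alpha = 0.05, power = 0.8, u = 3,
                                   ncp = c("total_df", "n")) {
  ncp <- match.arg(ncp)
  check_number(n, "n", lower = 2)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(power, "power", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(u, "u", lower = 1)
  v <- n - u - 1
  if (v < 1) {
    abort("`n` must exceed u + 1 (positive denominator df).",
          class = "gaitmos_config_error")
  }
  mult <- if (ncp == "n") n else u + v
  crit <- qf(1 - alpha, u, v)
  pw <- function(f2) 1 - pf(crit, u, v, ncp = f2 * mult)
  if (pw(1e6) < power) {
    abort("target power unattainable at this design.",
          class = "gaitmos_config_error")
  }
  uniroot(function(f2) pw(f2) - power, c(1e-12, 1e6), tol = 1e-12)$root
}
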