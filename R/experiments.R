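#' Single-enzyme titration analysis
#'
#' Fits each whole-solution decay of an enzyme titration to the
#' two-component model with the free-NADH lifetime fixed (450 ps by
#' default) and tabulates the bound amplitude and bound lifetime against
#' enzyme concentration.
#'
#' @param decays A tibble with a `concentration` column (uM) and a `decay`
#'   list-column of decay histograms (e.g. from
#'   [simulate_solution_decay()]).
#' @param irf IRF tibble.
#' @param fix_tau1 Free-NAD(P)H lifetime to fix, ns.
#' @param weighting Residual weighting passed to [fit_config()].
#' @return A tibble with one row per solution: `concentration`, `alpha2`,
#'   `tau2`, `reduced_chi_squared`, `converged` (fit failures are recorded
#'   as non-converged rows with `NA` estimates, not raised).
#' @export
titration_analysis <- function(decays, irf, fix_tau1 = 0.45,
                               weighting = "neyman") {
  stopifnot(is.data.frame(decays), all(c("concentration", "decay") %in% names(decays)))
  cfg <- fit_config(2L, fix_tau = fix_tau1, weighting = weighting)
  rows <- purrr::map2(decays$concentration, decays$decay, function(conc, d) {
    fit <- tryCatch(fit_decay(d, irf, cfg), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        concentration = conc, alpha2 = NA_real_, tau2 = NA_real_,
        reduced_chi_squared = NA_real_, converged = FALSE
      ))
    }
    tibble::tibble(
      concentration = conc,
      alpha2 = fit$model$alpha[2],
      tau2 = fit$model$tau[2],
      reduced_chi_squared = fit$reduced_chi_squared,
      converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Linear regression through the origin with uncentered R-squared
#'
#' Fits `y = m x` with the intercept forced to zero and reports the slope,
#' its standard error and two-sided p-value, the 95% confidence interval of
#' the slope, and the coefficient of determination in its uncentered form
#' `1 - SS_res / sum(y^2)` — the convention of common graphing software
#' when a regression is forced through (0, 0). The Pearson correlation test
#' p-value is reported alongside, since "the p-value of the line" can refer
#' to either.
#'
#' @param x,y Numeric vectors (at least two distinct `x` values).
#' @param conf_level Confidence level for the slope interval.
#' @return A one-row tibble: `slope`, `slope_se`, `conf_low`, `conf_high`,
#'   `r_squared`, `p_value` (slope t-test), `p_value_cor`, `df`, `n`.
#' @export
regress_through_origin <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L) {
    stop("need at least two distinct x values for regression", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + 0)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[1])
  se <- sm$coefficients[1, 2]
  dfree <- fit$df.residual
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- 1 - ss_res / sum(y^2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  p_cor <- tryCatch(stats::cor.test(x, y)$p.value, error = function(e) NA_real_)
  tibble::tibble(
    slope = slope,
    slope_se = se,
    conf_low = slope - tcrit * se,
    conf_high = slope + tcrit * se,
    r_squared = r2,
    p_value = sm$coefficients[1, 4],
    p_value_cor = p_cor,
    df = dfree,
    n = length(x)
  )
}

#' Unmix NADH bound to two enzymes by fixed-lifetime fitting
#'
#' Fits each mixture decay to the three-component model with all lifetimes
#' fixed (free NADH 0.45 ns, NADH-MDH 1.2 ns, NADH-LDH 1.6 ns by default),
#' derives the FLIM-measured LDH fraction of the bound signal
#' `alpha_ldh / (alpha_ldh + alpha_mdh)`, and regresses it on the true
#' concentration fraction `[LDH]/([LDH]+[MDH])` with a line forced through
#' the origin.
#'
#' @param decays Tibble with columns `ldh`, `mdh` (uM) and a `decay`
#'   list-column, e.g. from [simulate_mixture_series()].
#' @param irf IRF tibble.
#' @param lifetimes Fixed lifetimes (ns): free, MDH-bound, LDH-bound.
#' @param weighting Residual weighting passed to [fit_config()].
#' @return A list of class `unmix_result`: `per_decay`, a tibble with the
#'   fitted amplitude triple and measured fraction per decay, and
#'   `regression`, the one-row tibble from [regress_through_origin()].
#' @export
unmix_mixtures <- function(decays, irf, lifetimes = c(0.45, 1.2, 1.6),
                           weighting = "neyman") {
  stopifnot(
    is.data.frame(decays),
    all(c("ldh", "mdh", "decay") %in% names(decays)),
    length(lifetimes) == 3L
  )
  cfg <- fit_config(3L, fix_tau = lifetimes, weighting = weighting)
  ord <- order(lifetimes)
  rank_free <- which(ord == 1L) # positions after the fit's tau-ascending sort
  rank_mdh <- which(ord == 2L)
  rank_ldh <- which(ord == 3L)
  rows <- purrr::pmap(
    list(decays$ldh, decays$mdh, decays$decay),
    function(ldh, mdh, d) {
      fit <- fit_decay(d, irf, cfg)
      a <- fit$model$alpha
      tibble::tibble(
        ldh = ldh, mdh = mdh,
        ratio_true = ldh / (ldh + mdh),
        alpha_free = a[rank_free],
        alpha_mdh = a[rank_mdh],
        alpha_ldh = a[rank_ldh],
        fraction_measured = a[rank_ldh] / (a[rank_ldh] + a[rank_mdh]),
        reduced_chi_squared = fit$reduced_chi_squared,
        converged = fit$converged
      )
    }
  )
  per_decay <- dplyr::bind_rows(rows)
  structure(
    list(
      per_decay = per_decay,
      regression = regress_through_origin(
        per_decay$ratio_true, per_decay$fraction_measured
      )
    ),
    class = "unmix_result"
  )
}

#' @export
print.unmix_result <- function(x, ...) {
  r <- x$regression
  cat(sprintf(
    "<unmix_result: %d decays, m = %.3f, R^2 = %.3f (p = %.2g)>\n",
    nrow(x$per_decay), r$slope, r$r_squared, r$p_value
  ))
  invisible(x)
}

group_comparison <- function(test, mean_a, mean_b, sd_a, sd_b, statistic, df,
                             p_value, alpha = 0.05) {
  tibble::tibble(
    test = test, mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
    statistic = statistic, df = df, p_value = p_value,
    significant = is.finite(p_value) & p_value < alpha
  )
}

#' Welch's unpaired two-sample t-test
#'
#' Unpaired t-test with Welch's correction for unequal variances
#' (Satterthwaite degrees of freedom), two-sided — the test used for
#' comparisons of lifetime variables across experimental replicates. Two
#' groups that are both constant and equal return `t = 0, p = 1` by
#' convention.
#'
#' @param a,b Replicate values per group (>= 2 each).
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: group means and SDs, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
welch_t_test <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(ht)) {
    # both groups essentially constant
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    ht <- list(
      statistic = if (equal) 0 else Inf,
      parameter = length(a) + length(b) - 2,
      p.value = if (equal) 1 else 0
    )
  }
  group_comparison(
    "welch_t", mean(a), mean(b), stats::sd(a), stats::sd(b),
    unname(ht$statistic), unname(ht$parameter), ht$p.value, alpha
  )
}

#' Ratio-paired t-test
#'
#' A paired t-test on the logarithm of the after/before ratios (one-sample
#' t-test of `log(after/before)` against zero, two-sided), appropriate for
#' strictly positive measurements such as redox ratios and intensities that
#' scale multiplicatively. A constant nonzero log-ratio has zero variance;
#' by convention this returns `p = 0` (and `p = 1` if after == before
#' exactly).
#'
#' @param before,after Paired replicate values (> 0, equal lengths).
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble as in [welch_t_test()].
#' @export
ratio_paired_t_test <- function(before, after, alpha = 0.05) {
  stopifnot(length(before) == length(after), length(before) >= 2L)
  if (any(before <= 0) || any(after <= 0)) {
    stop("ratio-paired test requires strictly positive values", call. = FALSE)
  }
  lr <- log(after / before)
  if (stats::sd(lr) < .Machine$double.eps^0.5 * max(1, abs(mean(lr)))) {
    # constant log-ratio: p = 1 for no change, p -> 0 for an exact shift
    zero <- isTRUE(all.equal(mean(lr), 0))
    ht <- list(
      statistic = if (zero) 0 else Inf * sign(mean(lr)),
      parameter = length(lr) - 1,
      p.value = if (zero) 1 else 0
    )
  } else {
    ht <- stats::t.test(lr, mu = 0)
  }
  group_comparison(
    "ratio_paired_t", mean(before), mean(after), stats::sd(before),
    stats::sd(after), unname(ht$statistic), unname(ht$parameter),
    ht$p.value, alpha
  )
}
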