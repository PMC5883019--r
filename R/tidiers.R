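#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reconvolution fit
#'
#' One row per fitted quantity: component amplitudes and lifetimes (with
#' fixed lifetimes flagged), the background level and, if co-fitted, the
#' IRF shift. Standard errors are reported for the optimizer's free
#' parameters where the covariance was estimable; amplitudes are reported
#' as normalized fractions, whose errors are not propagated from the raw
#' amplitude coefficients.
#'
#' @param x A `flim_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `fixed`.
#' @export
tidy.flim_fit <- function(x, ...) {
  m <- x$model
  k <- length(m$tau)
  se <- x$uncertainties
  get_se <- function(nm) if (nm %in% names(se)) unname(se[nm]) else NA_real_
  tibble::tibble(
    term = c(
      paste0("alpha", seq_len(k)), paste0("tau", seq_len(k)), "C",
      if (x$config$fit_shift) "shift"
    ),
    estimate = c(
      m$alpha, m$tau, m$background,
      if (x$config$fit_shift) m$shift
    ),
    std.error = c(
      rep(NA_real_, k),
      vapply(paste0("tau", seq_len(k)), get_se, numeric(1)),
      get_se("C"),
      if (x$config$fit_shift) get_se("shift")
    ),
    fixed = c(
      rep(FALSE, k), m$fixed_tau, FALSE,
      if (x$config$fit_shift) FALSE
    )
  )
}

#' One-row summary of a reconvolution fit
#'
#' @param x A `flim_fit`.
#' @param ... Unused.
#' @return A tibble: `n_components`, `tau_m`, `reduced_chi_squared`,
#'   `n_free_parameters`, `photons_used`, `converged`.
#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$model$tau),
    tau_m = mean_lifetime(x$model),
    reduced_chi_squared = x$reduced_chi_squared,
    n_free_parameters = x$n_free_parameters,
    photons_used = x$photons_used,
    converged = x$converged
  )
}

#' Tidy parameter maps into a long pixel table
#'
#' @param x A `flim_maps` from [fit_image()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, and one column per map.
#' @export
tidy.flim_maps <- function(x, ...) {
  nr <- nrow(x$alpha1)
  nc <- ncol(x$alpha1)
  tibble::tibble(
    row = rep(seq_len(nr), nc),
    col = rep(seq_len(nc), each = nr),
    alpha1 = as.vector(x$alpha1),
    tau1 = as.vector(x$tau1),
    tau2 = as.vector(x$tau2),
    tau_m = as.vector(x$tau_m),
    chisq = as.vector(x$chisq),
    intensity = as.vector(x$intensity)
  )
}

#' Plot a decay fit with residuals
#'
#' Measured counts (points, log scale) with the fitted reconvolution curve
#' overlaid.
#'
#' @param object A `flim_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_fit <- function(object, ...) {
  df <- tibble::tibble(
    time_ns = object$time_ns,
    counts = object$counts,
    fitted = object$fitted
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$counts),
      size = 0.6, alpha = 0.6, colour = "grey30"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d55e00") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (ns)", y = "photon counts",
      title = sprintf(
        "%d-component reconvolution fit (reduced χ² = %.2f)",
        length(object$model$tau), object$reduced_chi_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a parameter map
#'
#' @param object A `flim_maps`.
#' @param map Which map to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_maps <- function(object,
                               map = c("tau2", "alpha1", "tau1", "tau_m",
                                       "chisq", "intensity"),
                               ...) {
  map <- match.arg(map)
  df <- tidy.flim_maps(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data[[map]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = map) +
    ggplot2::theme_void()
}

#' Plot an unmixing result
#'
#' Measured LDH bound-fraction against the true concentration fraction with
#' the through-origin regression line.
#'
#' @param object An `unmix_result` from [unmix_mixtures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unmix_result <- function(object, ...) {
  r <- object$regression
  ggplot2::ggplot(
    object$per_decay,
    ggplot2::aes(x = .data$ratio_true, y = .data$fraction_measured)
  ) +
    ggplot2::geom_abline(
      intercept = 0, slope = r$slope, colour = "#0072b2"
    ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "[LDH] / ([LDH] + [MDH])",
      y = "measured α_LDH / (α_LDH + α_MDH)",
      title = sprintf("m = %.3f, R² = %.3f", r$slope, r$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
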