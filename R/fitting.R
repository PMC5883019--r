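#' Configuration for reconvolution fitting
#'
#' @param n_components Number of exponential components (1-3).
#' @param fix_tau Optional numeric vector of length `n_components`; entries
#'   give lifetimes (ns) to hold fixed, `NA` leaves that component free.
#'   A scalar fixes component 1 only (the free-NAD(P)H convention, e.g.
#'   `fix_tau = 0.45` for solutions).
#' @param fix_alpha Optional full vector of fractional amplitudes to hold
#'   fixed (all components); only the overall scale is then fitted. Partial
#'   amplitude fixing is not supported.
#' @param weighting Residual weighting: `"neyman"` (1/max(counts, 1), the
#'   TCSPC software convention) or `"poisson_mle"` (deviance residuals of
#'   the Poisson likelihood).
#' @param max_iterations,tolerance Levenberg-Marquardt stopping controls.
#' @param fit_shift If `TRUE`, co-fit a fractional-bin IRF offset.
#' @param tau_bounds Lifetime box constraints in ns.
#' @param snr_gate Minimum peak bin count required before fitting (0 = off).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_components = 2L,
                       fix_tau = NULL,
                       fix_alpha = NULL,
                       weighting = c("neyman", "poisson_mle"),
                       max_iterations = 200L,
                       tolerance = 1e-8,
                       fit_shift = FALSE,
                       tau_bounds = c(0.05, 10),
                       snr_gate = 0) {
  n_components <- as.integer(n_components)
  stopifnot(n_components >= 1L, n_components <= 3L, tolerance > 0)
  weighting <- match.arg(weighting)
  if (!is.null(fix_tau)) {
    if (length(fix_tau) == 1L && n_components > 1L) {
      fix_tau <- c(fix_tau, rep(NA_real_, n_components - 1L))
    }
    stopifnot(length(fix_tau) == n_components)
    if (any(!is.na(fix_tau) & fix_tau <= 0)) {
      stop("fixed lifetimes must be positive", call. = FALSE)
    }
  }
  if (!is.null(fix_alpha)) {
    stopifnot(length(fix_alpha) == n_components)
    if (any(is.na(fix_alpha))) {
      stop("fix_alpha must specify all components (partial fixing unsupported)",
        call. = FALSE
      )
    }
    fix_alpha <- fix_alpha / sum(fix_alpha)
  }
  structure(
    list(
      n_components = n_components, fix_tau = fix_tau, fix_alpha = fix_alpha,
      weighting = weighting, max_iterations = as.integer(max_iterations),
      tolerance = tolerance, fit_shift = fit_shift, tau_bounds = tau_bounds,
      snr_gate = snr_gate
    ),
    class = "fit_config"
  )
}

# Background starting value: mean of the bins preceding the rising edge
# (first bin exceeding 10% of the peak), falling back to the minimum count.
estimate_background0 <- function(counts) {
  rise <- which(counts > 0.1 * max(counts))[1]
  if (!is.na(rise) && rise > 3L) mean(counts[seq_len(rise - 2L)]) else min(counts)
}

# Expected-count curve for a parameter vector, shared by residuals and the
# final report. Components are kept in the order of `tau0`/`free_tau`.
build_curve <- function(p, layout, irf_norm, t, periodic = FALSE) {
  k <- layout$k
  tau <- layout$tau_fixed
  tau[layout$free_tau] <- p[layout$idx_tau]
  a <- if (layout$scale_only) p[[1]] * layout$fix_alpha else p[layout$idx_a]
  C <- p[layout$idx_C]
  irf <- irf_norm
  if (layout$fit_shift) irf <- shift_vector(irf_norm, p[layout$idx_shift])
  d <- numeric(length(t))
  for (i in seq_len(k)) d <- d + a[i] * exp(-t / tau[i])
  g <- conv_bins(irf, d, periodic = periodic)
  g[g < 0] <- 0
  list(mu = g + C, a = a, tau = tau, C = C,
       shift = if (layout$fit_shift) p[layout$idx_shift] else 0)
}

#' Fit a decay histogram by iterative reconvolution
#'
#' Estimates amplitudes, lifetimes, background and (optionally) an IRF shift
#' by Levenberg-Marquardt minimization of weighted residuals between the
#' measured histogram and the IRF-convolved multi-exponential model. Any
#' lifetime fixed in `config` is held at its given value; fitted amplitudes
#' are reported normalized to sum to one and components are sorted by
#' increasing lifetime. The fit is deterministic for identical inputs.
#'
#' @param hist Decay histogram tibble (columns `time_ns`, `counts`).
#' @param irf IRF tibble from [make_irf()] or numeric vector.
#' @param config A [fit_config()].
#' @param periodic Passed to the forward model (circular convolution).
#' @return An object of class `flim_fit`: the fitted [multi_exp_model()],
#'   `reduced_chi_squared`, per-free-parameter `uncertainties`,
#'   `n_free_parameters`, `converged`, `photons_used`, plus the fitted curve.
#'   Non-convergence is flagged, not raised.
#' @seealso [tidy.flim_fit()], [glance.flim_fit()], [select_model()]
#' @export
#' @examples
#' ax <- time_axis(128, 12.5)
#' irf <- make_irf(220, ax)
#' truth <- multi_exp_model(c(0.4, 0.6), c(0.45, 2.5), background = 2)
#' y <- decay_histogram(round(evaluate_model(truth, irf, ax, 5e4)), ax)
#' fit <- fit_decay(y, irf, fit_config(2, fix_tau = 0.45))
#' glance(fit)
fit_decay <- function(hist, irf, config = fit_config(), periodic = FALSE) {
  counts <- if (is.data.frame(hist)) hist$counts else hist
  axis <- if (is.data.frame(hist)) axis_of(hist) else NULL
  if (is.data.frame(irf)) {
    if (is.null(axis)) axis <- axis_of(irf)
    irf <- irf$density
  }
  stopifnot(!is.null(axis), length(irf) == axis$n_bins)
  if (sum(counts) <= 0) stop("histogram has no photons", call. = FALSE)
  if (config$snr_gate > 0 && max(counts) < config$snr_gate) {
    stop(sprintf(
      "peak counts %.0f below SNR gate %.0f", max(counts), config$snr_gate
    ), call. = FALSE)
  }
  n <- axis$n_bins
  t <- axis$time_ns
  irf_norm <- irf / sum(irf)
  k <- config$n_components

  free_tau <- if (is.null(config$fix_tau)) rep(TRUE, k) else is.na(config$fix_tau)
  tau_fixed <- numeric(k)
  tau_fixed[!free_tau] <- config$fix_tau[!free_tau]
  tau_init_pool <- c(0.4, 2.0, 3.5)
  scale_only <- !is.null(config$fix_alpha)

  C0 <- estimate_background0(counts)
  a_tot0 <- max(sum(counts) - n * C0, max(counts))
  # decay term amplitudes: total photons ~ sum_i a_i * sum(conv(irf, exp))
  # initialise with equal shares against a tau ~ 1 ns reference integral
  ref_int <- sum(exp(-t / 1.0))
  a0 <- rep(a_tot0 / (k * ref_int), k)

  p0 <- c()
  lower <- c()
  upper <- c()
  layout <- list(
    k = k, free_tau = free_tau, tau_fixed = tau_fixed,
    scale_only = scale_only, fix_alpha = config$fix_alpha,
    fit_shift = config$fit_shift
  )
  if (scale_only) {
    p0 <- sum(a0)
    lower <- 0
    upper <- Inf
    layout$idx_a <- integer(0)
  } else {
    p0 <- a0
    lower <- rep(0, k)
    upper <- rep(Inf, k)
    layout$idx_a <- seq_len(k)
  }
  if (any(free_tau)) {
    layout$idx_tau <- length(p0) + seq_len(sum(free_tau))
    p0 <- c(p0, tau_init_pool[seq_len(k)][free_tau])
    lower <- c(lower, rep(config$tau_bounds[1], sum(free_tau)))
    upper <- c(upper, rep(config$tau_bounds[2], sum(free_tau)))
  } else {
    layout$idx_tau <- integer(0)
  }
  layout$idx_C <- length(p0) + 1L
  p0 <- c(p0, max(C0, 0))
  lower <- c(lower, 0)
  upper <- c(upper, Inf)
  if (config$fit_shift) {
    layout$idx_shift <- length(p0) + 1L
    p0 <- c(p0, 0)
    lower <- c(lower, -10)
    upper <- c(upper, 10)
  }

  w_ney <- 1 / sqrt(pmax(counts, 1))
  resid_fn <- function(p) {
    mu <- build_curve(p, layout, irf_norm, t, periodic)$mu
    if (config$weighting == "neyman") {
      (counts - mu) * w_ney
    } else {
      mu <- pmax(mu, 1e-12)
      dev <- 2 * (mu - counts + ifelse(counts > 0, counts * log(counts / mu), 0))
      sign(counts - mu) * sqrt(pmax(dev, 0))
    }
  }

  res <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations,
      ftol = config$tolerance, ptol = config$tolerance
    )
  )
  converged <- res$info %in% 1:4
  cur <- build_curve(res$par, layout, irf_norm, t, periodic)

  n_free <- length(p0)
  dof <- max(n - n_free, 1L)
  red_chisq <- sum(((counts - cur$mu) * w_ney)^2) / dof

  se <- rep(NA_real_, n_free)
  cov <- tryCatch(
    solve(res$hessian) * (res$deviance / dof),
    error = function(e) NULL
  )
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  par_names <- c(
    if (scale_only) "scale" else paste0("a", seq_len(k)),
    if (any(free_tau)) paste0("tau", which(free_tau)),
    "C",
    if (config$fit_shift) "shift"
  )
  names(se) <- par_names

  alpha_hat <- cur$a / sum(cur$a)
  model <- multi_exp_model(
    alpha = alpha_hat, tau = cur$tau, background = cur$C, shift = cur$shift,
    fixed_tau = !free_tau
  )
  structure(
    list(
      model = model,
      reduced_chi_squared = red_chisq,
      uncertainties = se,
      n_free_parameters = n_free,
      converged = converged,
      photons_used = sum(counts),
      fitted = cur$mu,
      counts = counts,
      time_ns = t,
      config = config
    ),
    class = "flim_fit"
  )
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit: %d components, reduced chi-squared %.3f, %s>\n",
    length(x$model$tau), x$reduced_chi_squared,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$model)
  invisible(x)
}

#' Choose the number of decay components by chi-squared improvement
#'
#' Fits each candidate model order and keeps the smallest order whose
#' reduced chi-squared is not improved by the next larger order by more than
#' `improvement` (relative). This mirrors the practice of adopting a
#' two-exponential model when a three-exponential fit does not improve the
#' chi-squared goodness of fit.
#'
#' @inheritParams fit_decay
#' @param orders Increasing candidate component counts (>= 2 candidates).
#' @param improvement Relative reduced-chi-squared reduction required to
#'   justify the larger model (default 0.05).
#' @param base_config `fit_config` template; `n_components` is overridden
#'   per candidate (fixed lifetimes, if any, are dropped for orders they do
#'   not cover).
#' @return A list: `order` (chosen), `fits` (per-order `flim_fit`s, named by
#'   order), and `table`, a tibble of order vs reduced chi-squared.
#' @export
select_model <- function(hist, irf, orders = c(1L, 2L, 3L), improvement = 0.05,
                         base_config = fit_config()) {
  orders <- sort(unique(as.integer(orders)))
  stopifnot(length(orders) >= 2L)
  fits <- list()
  for (k in orders) {
    cfg <- base_config
    cfg$n_components <- k
    if (!is.null(cfg$fix_tau)) cfg$fix_tau <- rep_len(c(cfg$fix_tau, NA_real_), k)
    if (!is.null(cfg$fix_alpha)) cfg$fix_alpha <- NULL
    fit <- tryCatch(fit_decay(hist, irf, cfg), error = function(e) {
      warning(sprintf("order %d fit failed: %s", k, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) fits[[as.character(k)]] <- fit
  }
  if (length(fits) == 0L) stop("all candidate fits failed", call. = FALSE)
  ok_orders <- as.integer(names(fits))
  chisq <- vapply(fits, function(f) f$reduced_chi_squared, numeric(1))
  chosen <- ok_orders[length(ok_orders)]
  for (i in seq_len(length(ok_orders) - 1L)) {
    if (chisq[i + 1L] >= (1 - improvement) * chisq[i]) {
      chosen <- ok_orders[i]
      break
    }
  }
  list(
    order = chosen,
    fits = fits,
    table = tibble::tibble(order = ok_orders, reduced_chi_squared = unname(chisq))
  )
}

# 2-D sliding-window (box) sum with edge truncation, via summed-area table.
box_sum <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(nr)
  j <- seq_len(nc)
  i2 <- pmin(i + r, nr) + 1L
  i1 <- pmax(i - r - 1L, 0L) + 1L
  j2 <- pmin(j + r, nc) + 1L
  j1 <- pmax(j - r - 1L, 0L) + 1L
  S[i2, j2] - S[i1, j2] - S[i2, j1] + S[i1, j1]
}

#' Spatially bin the decays of a FLIM stack
#'
#' Each output pixel's histogram is the sum of counts over the
#' (2r+1) x (2r+1) sliding window centered on it, truncated at image edges.
#' `bin_radius = 1` gives the 3x3 binning used for cellular analysis;
#' `whole_image = TRUE` sums every pixel into one whole-solution decay.
#'
#' @param stack A [flim_image()] or 3-D array (rows x cols x time bins).
#' @param bin_radius Non-negative integer window radius (0 = identity).
#' @param whole_image If `TRUE`, return a single summed decay histogram.
#' @return A 3-D array of binned counts with the input's dimensions, or a
#'   `flim_decay` tibble when `whole_image = TRUE`.
#' @export
bin_pixels <- function(stack, bin_radius = 1L, whole_image = FALSE) {
  counts <- if (inherits(stack, "flim_image")) stack$counts else stack
  axis <- if (inherits(stack, "flim_image")) stack$axis else NULL
  stopifnot(length(dim(counts)) == 3L, bin_radius >= 0L)
  nb <- dim(counts)[3]
  if (whole_image) {
    if (is.null(axis)) axis <- time_axis(nb)
    return(decay_histogram(apply(counts, 3L, sum), axis))
  }
  if (bin_radius == 0L) return(counts)
  out <- counts
  for (b in seq_len(nb)) out[, , b] <- box_sum(counts[, , b], bin_radius)
  out
}
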