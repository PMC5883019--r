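test_that("noiseless two-component decays are recovered exactly", {
  truth <- multi_exp_model(c(0.4, 0.6), c(0.45, 2.5))
  mu <- evaluate_model(truth, irf256, ax256, amplitude_scale = 5e5)
  hist <- decay_histogram(mu, ax256)
  fit <- fit_decay(hist, irf256, fit_config(2, fix_tau = 0.45))
  expect_true(fit$converged)
  expect_equal(fit$model$alpha, c(0.4, 0.6), tolerance = 1e-3)
  expect_equal(fit$model$tau[2], 2.5, tolerance = 1e-3)
  expect_equal(sum(fit$model$alpha), 1)
})

test_that("neyman and poisson_mle weighting agree on noiseless data", {
  truth <- multi_exp_model(c(0.55, 0.45), c(0.5, 2.2), background = 3)
  mu <- evaluate_model(truth, irf128, ax128, amplitude_scale = 1e5)
  hist <- decay_histogram(mu, ax128)
  f1 <- fit_decay(hist, irf128, fit_config(2, weighting = "neyman"))
  f2 <- fit_decay(hist, irf128, fit_config(2, weighting = "poisson_mle"))
  expect_equal(f1$model$tau, f2$model$tau, tolerance = 1e-6)
  expect_equal(f1$model$alpha, f2$model$alpha, tolerance = 1e-6)
})

test_that("bound lifetimes are recovered within 5% across Poisson replicates", {
  for (tau2 in c(1.2, 1.6, 2.5)) {
    est <- fit_tau2_over_seeds(tau2, seeds = 1:20)
    rel_err <- abs(est - tau2) / tau2
    expect_lt(stats::median(rel_err), 0.05)
    # no significant bias at the 5% level
    bias_p <- stats::t.test((est - tau2) / tau2)$p.value
    expect_gt(bias_p, 0.05)
  }
})

test_that("three-component fixed-lifetime fits recover the free amplitude", {
  # ground truth follows the first LDH/MDH mixture: free amplitude 60.5%,
  # bound signal split by the concentration ratio
  mix <- mixture_table(ldh_mdh_mixtures())[1, ]
  af <- mix$alpha_free_pct / 100
  truth <- multi_exp_model(
    alpha = c(af, (1 - af) * (1 - mix$ratio), (1 - af) * mix$ratio),
    tau = c(0.45, 1.2, 1.6), background = 10
  )
  d <- simulate_solution_decay(truth, irf256, photons = 1e6, seed = 42)
  fit <- fit_decay(d, irf256, fit_config(3, fix_tau = c(0.45, 1.2, 1.6)))
  expect_lt(abs(fit$model$alpha[1] - af), 0.03)
})

test_that("reduced chi-squared is calibrated on correctly specified data", {
  truth <- multi_exp_model(c(0.5, 0.5), c(0.45, 2.0), background = 10)
  chisq <- vapply(1:20, function(s) {
    d <- simulate_solution_decay(truth, irf256, photons = 5e5, seed = s)
    fit_decay(d, irf256, fit_config(2, fix_tau = 0.45))$reduced_chi_squared
  }, numeric(1))
  expect_gt(stats::median(chisq), 0.8)
  expect_lt(stats::median(chisq), 1.2)
})

test_that("fixing a lifetime at its true value does not degrade the fit", {
  truth <- multi_exp_model(c(0.6, 0.4), c(0.45, 2.0), background = 10)
  diffs <- vapply(1:12, function(s) {
    d <- simulate_solution_decay(truth, irf256, photons = 5e5, seed = 100 + s)
    free <- fit_decay(d, irf256, fit_config(2))
    fixed <- fit_decay(d, irf256, fit_config(2, fix_tau = 0.45))
    fixed$reduced_chi_squared - free$reduced_chi_squared
  }, numeric(1))
  expect_lt(stats::median(diffs), 0.05)
})

test_that("fit_decay rejects empty histograms and gates on SNR", {
  empty <- decay_histogram(numeric(128))
  expect_error(fit_decay(empty, irf128), "no photons")
  weak <- decay_histogram(c(rep(0, 60), 5, rep(1, 67)))
  expect_error(
    fit_decay(weak, irf128, fit_config(2, snr_gate = 3000)),
    "SNR gate"
  )
})

test_that("uncertainties are reported for free parameters", {
  truth <- multi_exp_model(c(0.5, 0.5), c(0.45, 2.0), background = 10)
  d <- simulate_solution_decay(truth, irf256, photons = 5e5, seed = 3)
  fit <- fit_decay(d, irf256, fit_config(2, fix_tau = 0.45))
  expect_true(all(c("a1", "a2", "tau2", "C") %in% names(fit$uncertainties)))
  expect_true(all(is.finite(fit$uncertainties)))
  # tau2 must lie within ~4 SE of truth for a calibrated error bar
  expect_lt(abs(fit$model$tau[2] - 2.0), 4 * fit$uncertainties["tau2"] + 0.02)
})

test_that("model order selection follows the chi-squared improvement rule", {
  # clean two-component data -> order 2
  truth2 <- multi_exp_model(c(0.5, 0.5), c(0.45, 3.0), background = 10)
  d2 <- simulate_solution_decay(truth2, irf256, photons = 1e6, seed = 7)
  sel2 <- select_model(d2, irf256, orders = c(1, 2, 3))
  expect_equal(sel2$order, 2)
  # single-component data -> order 1 preferred over 2
  truth1 <- multi_exp_model(1, 2.13, background = 10)
  d1 <- simulate_solution_decay(truth1, irf256, photons = 1e6, seed = 8)
  sel1 <- select_model(d1, irf256, orders = c(1, 2))
  expect_equal(sel1$order, 1)
})

test_that("well-separated three-component data selects order 3 over 2", {
  truth3 <- multi_exp_model(
    c(0.4, 0.35, 0.25), c(0.3, 1.5, 4.5), background = 10
  )
  d3 <- simulate_solution_decay(truth3, irf256, photons = 5e6, seed = 9)
  sel <- select_model(d3, irf256, orders = c(2, 3))
  expect_equal(sel$order, 3)
})

test_that("pixel binning sums sliding windows with edge truncation", {
  arr <- array(1, dim = c(5, 6, 8))
  expect_identical(bin_pixels(arr, 0L), arr)
  b1 <- bin_pixels(arr, 1L)
  expect_equal(b1[3, 3, 1], 9) # interior: full 3x3 window
  expect_equal(b1[1, 1, 1], 4) # corner: truncated to 2x2
  expect_equal(b1[1, 3, 1], 6) # edge: truncated to 2x3
  # whole-image collapse
  whole <- bin_pixels(arr, whole_image = TRUE)
  expect_s3_class(whole, "flim_decay")
  expect_equal(whole$counts, rep(30, 8))
  # binning conserves photons per bin up to window overlap: r = 0 identity
  set.seed(2)
  arr2 <- array(stats::rpois(5 * 6 * 8, 3), dim = c(5, 6, 8))
  b2 <- bin_pixels(arr2, 1L)
  # oracle: direct window sum at an interior pixel
  expect_equal(b2[3, 4, 2], sum(arr2[2:4, 3:5, 2]))
})

test_that("fitting is deterministic for identical inputs", {
  truth <- multi_exp_model(c(0.6, 0.4), c(0.45, 1.6), background = 10)
  d <- simulate_solution_decay(truth, irf256, photons = 5e5, seed = 21)
  f1 <- fit_decay(d, irf256, fit_config(2, fix_tau = 0.45))
  f2 <- fit_decay(d, irf256, fit_config(2, fix_tau = 0.45))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$reduced_chi_squared, f2$reduced_chi_squared)
})
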