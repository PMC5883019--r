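# Shared fixtures: a full-resolution axis for solution work and a coarser
# one for per-pixel image fits, plus their synthetic 220 ps IRFs.

ax256 <- time_axis(256, 12.5)
ax128 <- time_axis(128, 12.5)
irf256 <- make_irf(220, ax256)
irf128 <- make_irf(220, ax128)

# A discrete delta "IRF" at the first bin (reconvolution becomes identity).
delta_irf <- function(axis) c(1, numeric(axis$n_bins - 1L))

# Median fitted bound lifetime over Poisson replicates of a two-component
# solution decay with the free lifetime fixed at 450 ps.
fit_tau2_over_seeds <- function(tau2, seeds, alpha2 = 0.4, photons = 1e6,
                                background = 10, irf = irf256) {
  truth <- multi_exp_model(
    alpha = c(1 - alpha2, alpha2), tau = c(0.45, tau2),
    background = background
  )
  vapply(seeds, function(s) {
    d <- simulate_solution_decay(truth, irf, photons = photons, seed = s)
    fit_decay(d, irf, fit_config(2, fix_tau = 0.45))$model$tau[2]
  }, numeric(1))
}
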