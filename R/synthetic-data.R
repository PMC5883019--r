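# Evaluate expr with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic Gaussian instrument response function
#'
#' A discrete Gaussian IRF with the requested full width at half maximum,
#' peaked at 10% of the measurement window and normalized to unit sum. The
#' 220 ps default matches a second-harmonic-generation IRF measurement on a
#' TCSPC multiphoton system.
#'
#' @param fwhm_ps Full width at half maximum in picoseconds; must be below a
#'   quarter of the window.
#' @param axis A [time_axis()].
#' @return A tibble of class `flim_irf` with columns `time_ns`, `density`.
#' @export
#' @examples
#' irf <- make_irf(220, time_axis())
#' sum(irf$density) # 1
make_irf <- function(fwhm_ps = 220, axis = time_axis()) {
  fwhm_ns <- fwhm_ps / 1000
  if (fwhm_ns <= 0) stop("fwhm must be positive", call. = FALSE)
  if (fwhm_ns >= axis$window / 4) {
    stop("IRF FWHM must be below a quarter of the measurement window", call. = FALSE)
  }
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  center <- 0.1 * axis$window
  d <- exp(-(axis$time_ns - center)^2 / (2 * sigma^2))
  out <- tibble::new_tibble(
    list(time_ns = axis$time_ns, density = d / sum(d)),
    nrow = axis$n_bins,
    class = "flim_irf"
  )
  attr(out, "fwhm_ps") <- fwhm_ps
  out
}

#' Measure the FWHM of a sampled peak
#'
#' Linear-interpolated full width at half maximum of a single-peaked curve,
#' in the units of `time`.
#'
#' @param time Sample positions.
#' @param y Sampled values (single dominant peak).
#' @return FWHM in the units of `time`.
#' @export
measure_fwhm <- function(time, y) {
  ip <- which.max(y)
  half <- y[ip] / 2
  cross <- function(i1, i2) {
    # linear interpolation between two samples straddling the half maximum
    time[i1] + (half - y[i1]) * (time[i2] - time[i1]) / (y[i2] - y[i1])
  }
  left <- max(which(y[seq_len(ip)] < half))
  right <- ip - 1L + min(which(y[ip:length(y)] < half))
  cross(right, right - 1L) - cross(left, left + 1L)
}

#' Photon budget that yields a target peak bin count
#'
#' @param model A [multi_exp_model()].
#' @param irf IRF tibble or vector.
#' @param axis Time axis (defaults to the IRF's).
#' @param peak Target expected peak bin count.
#' @return Total signal photons such that the expected peak equals `peak`.
#' @export
photons_for_peak <- function(model, irf, axis = NULL, peak = 3000) {
  mu1 <- evaluate_model(model, irf, axis, amplitude_scale = 1)
  peak / max(mu1 - model$background)
}

#' Simulate a TCSPC solution decay with Poisson noise
#'
#' Draws independent Poisson counts around the expected decay curve of
#' `model` scaled to a total signal photon budget (the model's background
#' adds `background * n_bins` photons in expectation). The default budget
#' puts the expected peak at 10000 counts, comfortably above the peak-3000
#' quality gate used for whole-solution decays.
#'
#' @param model A [multi_exp_model()] (ground truth).
#' @param irf IRF tibble from [make_irf()].
#' @param photons Total expected signal photons; `NULL` targets peak 10000.
#' @param seed Optional integer seed (local to this call).
#' @param axis Time axis; defaults to the IRF's.
#' @return A `flim_decay` tibble; the generating model is attached as
#'   attribute `"truth"`.
#' @export
simulate_solution_decay <- function(model, irf, photons = NULL, seed = NULL,
                                    axis = NULL) {
  if (is.null(axis) && is.data.frame(irf)) axis <- axis_of(irf)
  if (is.null(photons)) photons <- photons_for_peak(model, irf, axis, peak = 10000)
  if (photons <= 0) stop("photon budget must be positive", call. = FALSE)
  mu <- evaluate_model(model, irf, axis, amplitude_scale = photons)
  counts <- with_local_seed(seed, stats::rpois(length(mu), mu))
  out <- decay_histogram(counts, axis)
  attr(out, "truth") <- model
  out
}

#' The four-mixture LDH/MDH solution design
#'
#' The enzyme concentrations (uM) of the four NADH-MDH-LDH mixtures used to
#' validate two-enzyme unmixing, together with the free-NADH amplitude (%)
#' measured in each solution. These printed values serve as inputs to the
#' mixture simulator and as the reference for the derived-column checks.
#'
#' @return A tibble with columns `mixture`, `ldh`, `mdh`, `alpha_free_pct`.
#' @export
ldh_mdh_mixtures <- function() {
  tibble::tibble(
    mixture = 1:4,
    ldh = c(4.9, 14.2, 1.4, 10.0),
    mdh = c(13.0, 2.6, 13.0, 8.0),
    alpha_free_pct = c(60.5, 48.0, 68.9, 42.6)
  )
}

#' Simulate replicate decays for a two-enzyme mixture series
#'
#' For each design row, builds the three-component ground truth (free NADH
#' plus NADH bound to MDH and to LDH at the fixed unmixing lifetimes): the
#' free amplitude comes from the design's `alpha_free_pct` column and the
#' bound amplitude is split between the two enzymes in proportion to their
#' concentrations — the proportionality the through-origin regression is
#' designed to validate. Alternatively (`truth_rule = "equilibrium"`) the
#' split and free fraction come from the competitive binding solver.
#'
#' @param design Mixture design; default [ldh_mdh_mixtures()]. Needs `ldh`,
#'   `mdh` and (for the default rule) `alpha_free_pct` columns.
#' @param irf IRF tibble.
#' @param lifetimes Component lifetimes (ns): free, MDH-bound, LDH-bound.
#' @param photons Signal photon budget per decay.
#' @param background Background counts per bin.
#' @param replicates Replicate decays per mixture.
#' @param seed Base seed; replicate r of mixture m uses `seed + 97*m + r`.
#' @param truth_rule `"measured"` (design's free-amplitude column) or
#'   `"equilibrium"` (competitive solver with `ligand`, `kd`, `sites`).
#' @param ligand,kd,sites Equilibrium-rule parameters (uM; per-enzyme
#'   vectors for `kd`/`sites`, order MDH then LDH).
#' @return A tibble with one row per simulated decay: design columns, true
#'   amplitudes (`alpha_free`, `alpha_mdh`, `alpha_ldh`), the true LDH
#'   fraction `ratio_true`, `replicate`, `seed`, and a `decay` list-column.
#' @export
simulate_mixture_series <- function(design = ldh_mdh_mixtures(),
                                    irf = make_irf(),
                                    lifetimes = c(0.45, 1.2, 1.6),
                                    photons = 1e6,
                                    background = 10,
                                    replicates = 3L,
                                    seed = 1L,
                                    truth_rule = c("measured", "equilibrium"),
                                    ligand = 50, kd = c(25, 8.8),
                                    sites = c(2L, 4L)) {
  stopifnot(nrow(design) >= 2L, length(lifetimes) == 3L)
  truth_rule <- match.arg(truth_rule)
  design <- mixture_table(design)
  alpha_free <- if (truth_rule == "measured") {
    stopifnot("alpha_free_pct" %in% names(design))
    design$alpha_free_pct / 100
  } else {
    vapply(
      seq_len(nrow(design)),
      function(i) {
        predict_free_fraction(ligand, c(design$mdh[i], design$ldh[i]), kd, sites)
      },
      numeric(1)
    )
  }
  if (any(alpha_free < 0 | alpha_free > 1)) {
    stop("truth rule produced amplitudes outside [0, 1]", call. = FALSE)
  }
  rows <- tidyr::expand_grid(
    design,
    alpha_free = NA_real_,
    replicate = seq_len(replicates)
  )
  rows$alpha_free <- rep(alpha_free, each = replicates)
  rows$alpha_ldh <- (1 - rows$alpha_free) * rows$ratio
  rows$alpha_mdh <- (1 - rows$alpha_free) * (1 - rows$ratio)
  rows$seed <- seed + 97L * rep(seq_len(nrow(design)), each = replicates) +
    rows$replicate
  rows$decay <- purrr::pmap(
    list(rows$alpha_free, rows$alpha_mdh, rows$alpha_ldh, rows$seed),
    function(af, am, al, s) {
      truth <- multi_exp_model(
        alpha = c(af, am, al), tau = lifetimes, background = background
      )
      simulate_solution_decay(truth, irf, photons = photons, seed = s)
    }
  )
  rows
}

#' Specification of a synthetic two-channel cell scene
#'
#' Describes a field of non-overlapping elliptical cells with concentric
#' nuclei. Per-cell decay parameters are drawn from truncated normal
#' distributions chosen to sit inside typical cytoplasmic NAD(P)H ranges
#' (bound lifetime around 2.4-2.9 ns); they are plausible stand-ins, not
#' measured population values. The default geometry matches a 256 x 256
#' pixel acquisition with 256 time bins.
#'
#' @param shape Image dimensions (rows, cols) in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_radius_px,nucleus_fraction Cell semi-axis range (px) and
#'   nucleus/cell size ratio.
#' @param alpha1_mean,alpha1_sd Free-NAD(P)H amplitude distribution.
#' @param tau1_mean,tau1_sd Free lifetime distribution (ns).
#' @param tau2_mean,tau2_sd Bound lifetime distribution (ns).
#' @param redox_mean,redox_sd Per-cell optical redox ratio distribution.
#' @param photons_per_pixel Expected signal photons per cytoplasm pixel.
#'   The default 300 puts roughly 2700 photons in each 3x3-binned decay,
#'   enough for a stable two-component fit while keeping the binned peak
#'   (~90 counts) far above the cellular SNR gate of 15.
#' @param background_photons Expected photons per background pixel.
#' @param axis Time axis of the FLIM channel.
#' @param seed Integer seed.
#' @return An object of class `scene_spec` (a list of the above).
#' @export
scene_spec <- function(shape = c(256L, 256L),
                       n_cells = 20L,
                       cell_radius_px = c(8, 14),
                       nucleus_fraction = 0.45,
                       alpha1_mean = 0.75, alpha1_sd = 0.03,
                       tau1_mean = 0.6, tau1_sd = 0.1,
                       tau2_mean = 2.7, tau2_sd = 0.2,
                       redox_mean = 1.4, redox_sd = 0.15,
                       photons_per_pixel = 300,
                       background_photons = 1,
                       axis = time_axis(),
                       seed = 1L) {
  structure(
    list(
      shape = as.integer(shape), n_cells = as.integer(n_cells),
      cell_radius_px = cell_radius_px, nucleus_fraction = nucleus_fraction,
      alpha1_mean = alpha1_mean, alpha1_sd = alpha1_sd,
      tau1_mean = tau1_mean, tau1_sd = tau1_sd,
      tau2_mean = tau2_mean, tau2_sd = tau2_sd,
      redox_mean = redox_mean, redox_sd = redox_sd,
      photons_per_pixel = photons_per_pixel,
      background_photons = background_photons,
      axis = axis, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' 3-D FLIM photon-count stack
#'
#' @param counts 3-D array (rows x cols x time bins) of photon counts.
#' @param axis A [time_axis()].
#' @param channel Fluorophore channel label (`"NADPH"` or `"FAD"`).
#' @param fov_um Physical field of view (um); default 270.
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(counts, axis = time_axis(dim(counts)[3]),
                       channel = c("NADPH", "FAD"), fov_um = 270) {
  stopifnot(length(dim(counts)) == 3L, dim(counts)[3] == axis$n_bins)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(
    list(counts = counts, axis = axis, channel = match.arg(channel),
         fov_um = fov_um),
    class = "flim_image"
  )
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<flim_image: %d x %d px, %d bins, channel %s, %s photons>\n",
    d[1], d[2], d[3], x$channel, format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' Simulate a two-channel FLIM cell scene with ground truth
#'
#' Places non-overlapping elliptical cells (rejection sampling on ellipse
#' overlap, capped attempts), draws per-cell decay parameters and redox
#' ratio from the spec's distributions, then draws Poisson photon counts:
#' cytoplasm pixels from the cell's two-component decay model, nucleus
#' pixels from a dimmer variant, background pixels near zero. The FAD
#' intensity channel is scaled so each cell's expected NAD(P)H/FAD ratio
#' equals its drawn redox truth.
#'
#' @param spec A [scene_spec()].
#' @param irf IRF tibble matching `spec$axis` (default synthetic 220 ps).
#' @return A list: `nadph` ([flim_image()]), `fad` (intensity matrix),
#'   `masks` (list of `cell` and `nucleus` label matrices), and `truth`, a
#'   tibble of per-cell generating parameters.
#' @export
simulate_cell_scene <- function(spec = scene_spec(),
                                irf = make_irf(220, spec$axis)) {
  with_local_seed(spec$seed, {
    nr <- spec$shape[1]
    nc <- spec$shape[2]
    nb <- spec$axis$n_bins
    cell <- matrix(0L, nr, nc)
    nuc <- matrix(0L, nr, nc)
    cx <- numeric(0); cy <- numeric(0); ca <- numeric(0); cb <- numeric(0)
    max_attempts <- 200L * spec$n_cells
    attempts <- 0L
    placed <- 0L
    while (placed < spec$n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place all cells without overlap; reduce n_cells or ",
             "radius, or change the seed", call. = FALSE)
      }
      a <- stats::runif(1, spec$cell_radius_px[1], spec$cell_radius_px[2])
      b <- stats::runif(1, spec$cell_radius_px[1], spec$cell_radius_px[2])
      x <- stats::runif(1, a + 1, nr - a - 1)
      y <- stats::runif(1, b + 1, nc - b - 1)
      if (placed > 0) {
        # conservative circle test on the larger semi-axes, 2 px margin
        d2 <- (cx - x)^2 + (cy - y)^2
        if (any(d2 < (pmax(ca, cb) + max(a, b) + 2)^2)) next
      }
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y; ca[placed] <- a; cb[placed] <- b
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      inside <- ((rows - x) / a)^2 + ((cols - y) / b)^2 <= 1
      cell[inside] <- placed
      an <- a * spec$nucleus_fraction
      bn <- b * spec$nucleus_fraction
      inside_n <- ((rows - x) / an)^2 + ((cols - y) / bn)^2 <= 1
      nuc[inside_n] <- placed
    }
    n_cells <- placed
    truth <- tibble::tibble(
      cell = seq_len(n_cells),
      alpha1 = rnorm_trunc(n_cells, spec$alpha1_mean, spec$alpha1_sd, 0.02, 0.98),
      tau1 = rnorm_trunc(n_cells, spec$tau1_mean, spec$tau1_sd, 0.2, 1.2),
      tau2 = rnorm_trunc(n_cells, spec$tau2_mean, spec$tau2_sd, 1.4, 4.5),
      redox = rnorm_trunc(n_cells, spec$redox_mean, spec$redox_sd, 0.3, 5)
    )
    truth$tau_m <- truth$alpha1 * truth$tau1 + (1 - truth$alpha1) * truth$tau2

    counts <- array(0L, dim = c(nr, nc, nb))
    fad <- matrix(0, nr, nc)
    plane_size <- nr * nc
    # linear indices of plane pixels `px` replicated across all time bins
    stack_idx <- function(px) {
      rep(px, nb) + rep((seq_len(nb) - 1L) * plane_size, each = length(px))
    }
    fill_pixels <- function(px, mu) {
      if (length(px) == 0) return(invisible())
      draw <- stats::rpois(length(px) * nb, rep(mu, each = length(px)))
      counts[stack_idx(px)] <<- draw
    }
    bg_px <- which(cell == 0)
    fill_pixels(bg_px, rep(spec$background_photons / nb, nb))
    fad[bg_px] <- stats::rpois(length(bg_px), spec$background_photons)
    for (i in seq_len(n_cells)) {
      cyto <- which(cell == i & nuc != i)
      nucpx <- which(nuc == i)
      model <- multi_exp_model(
        alpha = c(truth$alpha1[i], 1 - truth$alpha1[i]),
        tau = c(truth$tau1[i], truth$tau2[i])
      )
      mu_cyto <- evaluate_model(model, irf, spec$axis,
        amplitude_scale = spec$photons_per_pixel
      )
      fill_pixels(cyto, mu_cyto)
      fill_pixels(nucpx, mu_cyto * 0.5) # nuclei dimmer, same lifetime family
      fad[cyto] <- stats::rpois(length(cyto), spec$photons_per_pixel / truth$redox[i])
      fad[nucpx] <- stats::rpois(
        length(nucpx), 0.5 * spec$photons_per_pixel / truth$redox[i]
      )
    }
    list(
      nadph = flim_image(counts, spec$axis, channel = "NADPH"),
      fad = fad,
      masks = list(cell = cell, nucleus = nuc),
      truth = truth
    )
  })
}
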