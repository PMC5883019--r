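# A small noiseless uniform stack: every pixel shares one decay model.
uniform_stack <- function(model, photons, nr = 8, nc = 8, axis = ax128,
                          irf = irf128) {
  mu <- evaluate_model(model, irf, axis, amplitude_scale = photons)
  counts <- array(rep(mu, each = nr * nc), dim = c(nr, nc, axis$n_bins))
  flim_image(counts, axis)
}

test_that("noiseless uniform images give constant parameter maps", {
  truth <- multi_exp_model(c(0.7, 0.3), c(0.6, 2.7))
  img <- uniform_stack(truth, photons = 500)
  maps <- fit_image(img, irf128)
  expect_equal(max(abs(maps$tau2 - 2.7)), 0, tolerance = 1e-3)
  expect_equal(max(abs(maps$alpha1 - 0.7)), 0, tolerance = 1e-3)
  expect_equal(
    maps$tau_m,
    maps$alpha1 * maps$tau1 + (1 - maps$alpha1) * maps$tau2,
    tolerance = 1e-9
  )
  expect_equal(unname(maps$intensity[1, 1]), 500, tolerance = 1e-6)
})

test_that("pixels below the SNR gate are NaN in lifetime maps", {
  truth <- multi_exp_model(c(0.7, 0.3), c(0.6, 2.7))
  img <- uniform_stack(truth, photons = 400, nr = 6, nc = 6)
  img$counts[1:2, , ] <- 0 # photon-starved rows
  maps <- fit_image(img, irf128)
  expect_true(all(is.nan(maps$tau2[1, ])))
  expect_true(all(is.finite(maps$tau2[5:6, ])))
  expect_error(
    fit_image(flim_image(array(0, c(4, 4, 128)), ax128), irf128),
    "no photons"
  )
})

test_that("redox ratio map is elementwise and gain-invariant", {
  a <- matrix(runif(36, 1, 5), 6, 6)
  expect_equal(redox_ratio_map(a, a), matrix(1, 6, 6))
  expect_equal(redox_ratio_map(2 * a, a), matrix(2, 6, 6))
  # common multiplicative gain cancels
  b <- matrix(runif(36, 1, 5), 6, 6)
  expect_equal(redox_ratio_map(3 * a, 3 * b), redox_ratio_map(a, b))
  # zero-FAD pixels are NaN
  b0 <- b
  b0[2, 2] <- 0
  expect_true(is.nan(redox_ratio_map(a, b0)[2, 2]))
  expect_error(redox_ratio_map(a, matrix(1, 2, 2)), "dimensions")
})

test_that("per-cell summaries use cytoplasm pixels only", {
  nr <- 10
  maps <- structure(
    list(
      alpha1 = matrix(0.5, nr, nr), tau1 = matrix(0.5, nr, nr),
      tau2 = matrix(2, nr, nr), tau_m = matrix(1.25, nr, nr),
      chisq = matrix(1, nr, nr), intensity = matrix(100, nr, nr)
    ),
    class = "flim_maps"
  )
  cellm <- matrix(0L, nr, nr)
  cellm[2:9, 2:9] <- 1L
  nucm <- matrix(0L, nr, nr)
  nucm[2:9, 2:5] <- 1L # nucleus covers half the cell
  # distinct values inside the nucleus must not leak into the means
  maps$tau2[nucm == 1L] <- 99
  tab <- per_cell_summary(maps, NULL, list(cell = cellm, nucleus = nucm))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$tau2, 2)
  expect_equal(tab$n_pixels, sum(cellm == 1L & nucm == 0L))
  # cells below the pixel floor are dropped with a warning
  cell2 <- cellm
  cell2[1, 1] <- 2L
  expect_warning(
    tab2 <- per_cell_summary(maps, NULL, list(cell = cell2, nucleus = nucm)),
    "dropping"
  )
  expect_false(2L %in% tab2$cell)
  # empty mask -> empty table with warning
  expect_warning(
    empty <- per_cell_summary(
      maps, NULL,
      list(cell = matrix(0L, nr, nr), nucleus = matrix(0L, nr, nr))
    ),
    "no cells"
  )
  expect_equal(nrow(empty), 0)
})

test_that("per-cell summaries are invariant to label renumbering", {
  sp <- scene_spec(
    shape = c(40, 40), n_cells = 3, cell_radius_px = c(5, 7),
    axis = ax128, photons_per_pixel = 200, seed = 12
  )
  sc <- simulate_cell_scene(sp, irf128)
  maps <- list(
    alpha1 = sc$fad * 0 + 0.5, tau1 = sc$fad * 0 + 0.5,
    tau2 = matrix(stats::runif(1600, 2, 3), 40, 40),
    tau_m = sc$fad * 0 + 1, chisq = sc$fad * 0 + 1, intensity = sc$fad
  )
  class(maps) <- "flim_maps"
  tab <- per_cell_summary(maps, NULL, sc$masks)
  # permute labels 1..3 -> 3,1,2
  perm <- c(3L, 1L, 2L)
  masks2 <- list(
    cell = matrix(ifelse(sc$masks$cell > 0, perm[pmax(sc$masks$cell, 1)], 0L), 40, 40),
    nucleus = matrix(ifelse(sc$masks$nucleus > 0, perm[pmax(sc$masks$nucleus, 1)], 0L), 40, 40)
  )
  tab2 <- per_cell_summary(maps, NULL, masks2)
  expect_equal(
    dplyr::arrange(dplyr::mutate(tab, cell = perm[cell]), cell)$tau2,
    dplyr::arrange(tab2, cell)$tau2
  )
})

test_that("generator scenes are recovered through the full image pipeline", {
  sp <- scene_spec(
    shape = c(48, 48), n_cells = 4, cell_radius_px = c(6, 9),
    axis = ax128, seed = 3
  )
  sc <- simulate_cell_scene(sp, irf128)
  maps <- fit_image(sc$nadph, irf128)
  redox <- redox_ratio_map(maps$intensity, sc$fad)
  tab <- per_cell_summary(maps, redox, sc$masks)
  joined <- dplyr::inner_join(tab, sc$truth, by = "cell",
                              suffix = c("_est", "_true"))
  expect_equal(nrow(joined), 4)
  # bound lifetime: median relative error across cells within 3%
  rel <- abs(joined$tau2_est - joined$tau2_true) / joined$tau2_true
  expect_lt(stats::median(rel), 0.03)
  # per-cell redox ratio within 2% of the drawn truth
  expect_lt(
    max(abs(joined$redox_ratio - joined$redox) / joined$redox), 0.02
  )
  # rank order of bound lifetime preserved
  expect_gte(
    stats::cor(joined$tau2_est, joined$tau2_true, method = "spearman"), 0.9
  )
})

test_that("control normalization rescales and is scale-invariant", {
  expect_equal(normalize_to_control(1.3, 1.3), 1)
  expect_equal(normalize_to_control(0.8, 1.0), 0.8)
  v <- c(0.8, 1.1, 0.9)
  expect_equal(
    normalize_to_control(5 * v, 5 * 1.2),
    normalize_to_control(v, 1.2)
  )
  expect_error(normalize_to_control(v, 0), "positive")
})

test_that("FLIM stacks round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  sp <- scene_spec(
    shape = c(16, 16), n_cells = 1, cell_radius_px = c(4, 5),
    axis = time_axis(32), photons_per_pixel = 100, seed = 4
  )
  sc <- simulate_cell_scene(sp, make_irf(220, time_axis(32)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_flim_tiff(sc$nadph, path)
  back <- read_flim_tiff(path, time_axis(32))
  expect_equal(back$counts, sc$nadph$counts + 0) # integer -> double
})
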