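kern <- spatial_kernels()

test_that("kernel Fourier coefficients follow the Gaussian decay law", {
  kf0 <- kernel_fourier(kern, 0, 0, 0)
  expect_equal(kf0$EX, unname(kern$wbar["E", "X"]))   # zero mode = total weight
  expect_equal(kf0$EE, unname(kern$wbar["E", "E"]))
  kf1 <- kernel_fourier(kern, 1, 0, 0)
  expect_equal(kf1$EE / kf0$EE, exp(-2 * pi^2 * 0.15^2), tolerance = 1e-12)
  # strict decay in spatial and orientation frequency
  n <- 0:6
  expect_true(all(diff(kernel_fourier(kern, n)$EE) < 0))
  expect_true(all(diff(kernel_fourier(kern, 0, 0, n)$IX) < 0))
})

test_that("width calculus reproduces the balanced-width arithmetic", {
  # no divergence: all widths collapse onto the stimulus width
  wm0 <- gaussian_widths(0.1, 1e-9, 1e-9, 1e-9)
  expect_equal(wm0$beta_X, 0.1, tolerance = 1e-8)
  expect_equal(wm0$sigma_E, 0.1, tolerance = 1e-8)

  wm <- gaussian_widths(0.2, 0.04, 0.15, 0.04)
  expect_true(wm$feasible)
  expect_equal(wm$beta_X, 0.2039608, tolerance = 1e-6)
  expect_equal(wm$sigma_E, 0.1382027, tolerance = 1e-6)
  expect_equal(wm$sigma_I, 0.2, tolerance = 1e-9)

  bad <- gaussian_widths(0.06, 0.04, 0.15, 0.04)
  expect_false(bad$feasible)
  expect_true(is.na(bad$sigma_E))
  expect_equal(bad$sigma_I, sqrt(0.0052 - 0.0016), tolerance = 1e-9)
})

test_that("stimulus builder calibrates and degenerates correctly", {
  # floors absorb everything: uniform field at rbar_X
  u <- build_stimulus(stimulus_spec(c = 1, c_theta = 1, rbar_X = 7,
                                    calibrate = NULL), c(16, 16, 4))
  expect_equal(range(u), c(7, 7))

  # calibration pins the spatial factor to [10, 20] Hz
  st <- build_stimulus(stimulus_spec(sigma_X = 0.2), c(64, 64, 8))
  spatial_factor <- unclass(st)[, , 1] / (0.75 + 0.25 *
    wrapped_gaussian(-0.5, 0.1))
  expect_equal(min(spatial_factor), 10, tolerance = 1e-6)
  expect_equal(max(spatial_factor), 20, tolerance = 1e-6)

  # disc: center at rbar, far outside at the baseline
  dsc <- build_stimulus(stimulus_spec("disc", sigma_X = 0.1, blur = 1e-9,
                                      rbar_X = 20, c = 0.5, calibrate = NULL),
                        c(64, 64, 1))
  expect_equal(dsc[33, 33, 1], 20, tolerance = 1e-6)
  expect_equal(dsc[1, 1, 1], 10, tolerance = 1e-6)

  expect_error(build_stimulus(stimulus_spec(), c(2, 2, 1)), "at least 4")
  expect_error(stimulus_spec("contrast_map", contrast = matrix(-1, 4, 4)),
               "non-negative")
})

test_that("uniform input reduces the spatial solvers to the discrete ones", {
  u <- build_stimulus(stimulus_spec(c = 1, c_theta = 1, rbar_X = 5,
                                    calibrate = NULL), c(16, 16, 4))
  mf <- build_meanfield(coupling_table(), population_sizes(N = 2e5, N_X = 1.6e5))
  X <- external_drive(mf, 5)
  sol <- spatial_corrected_rates(kern, u, gain = 15)
  rd <- corrected_rates(mf$W, X, kern$epsilon, 15)$r
  expect_equal(as.numeric(sol$rE), rep(rd[1], 16 * 16 * 4), tolerance = 1e-10)
  expect_equal(as.numeric(sol$rI), rep(rd[2], 16 * 16 * 4), tolerance = 1e-10)

  bal <- spatial_balanced_rates(kern, u)
  rb <- balanced_rates(mf$W, X)$r
  expect_equal(mean(bal$rE), rb[1], tolerance = 1e-10)
  expect_equal(mean(bal$rI), rb[2], tolerance = 1e-10)
})

test_that("Fourier solver equals a dense real-space solve on a coarse grid", {
  rX <- random_smooth_field(c(8, 8, 4))
  sol <- spatial_corrected_rates(kern, rX, gain = 15)
  oracle <- dense_spatial_solve(kern, rX, kern$epsilon, 15)
  expect_equal(as.numeric(sol$rE), as.numeric(oracle$rE),
               tolerance = 1e-10)
  expect_equal(as.numeric(sol$rI), as.numeric(oracle$rI),
               tolerance = 1e-10)
})

test_that("domain averages equal the zero Fourier mode (global balance)", {
  st <- build_stimulus(stimulus_spec(sigma_X = 0.2), c(32, 32, 8))
  sol <- spatial_corrected_rates(kern, st, gain = 15)
  rtE0 <- Re(stats::fft(unclass(sol$rE))[1, 1, 1]) / length(sol$rE)
  expect_equal(mean(sol$rE), rtE0, tolerance = 1e-12)

  # local imbalance with global balance: as epsilon shrinks, the local
  # deviation of the narrow-stimulus solution grows relative to the
  # deviation of its network average from the uniform balanced average
  stn <- build_stimulus(stimulus_spec(sigma_X = 0.06), c(32, 32, 8))
  mf <- build_meanfield(coupling_table(), population_sizes(N = 2e5, N_X = 1.6e5))
  ratio <- vapply(10^-(3:5), function(e) {
    sol <- spatial_corrected_rates(kern, stn, epsilon = e, gain = 15)
    avg_X <- mean(stn)
    glob_bal <- balanced_rates(mf$W, external_drive(mf, 1) * avg_X)$r[1]
    peak_dev <- max(abs(sol$rE - mean(sol$rE)))
    mean_dev <- abs(mean(sol$rE) - glob_bal)
    peak_dev / mean_dev
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("balanced solver matches width theory and refuses sharp input", {
  st <- build_stimulus(stimulus_spec(sigma_X = 0.2), c(64, 64, 16))
  bal <- spatial_balanced_rates(kern, st)
  wm <- gaussian_widths(0.2, 0.04, 0.15, 0.04)
  fitE <- fit_profile_width(bal$rE, "x")
  fitI <- fit_profile_width(bal$rI, "x")
  expect_equal(fitE$sigma, wm$sigma_E, tolerance = (1 / 64) / wm$sigma_E)
  expect_equal(fitI$sigma, wm$sigma_I, tolerance = (1 / 64) / wm$sigma_I)

  # width recovery across a feasible parameter sweep
  for (sx in c(0.16, 0.25)) {
    stx <- build_stimulus(stimulus_spec(sigma_X = sx), c(64, 64, 8))
    wmx <- gaussian_widths(sx, 0.04, 0.15, 0.04)
    fx <- fit_profile_width(spatial_balanced_rates(kern, stx)$rE, "x")
    expect_equal(fx$sigma, wmx$sigma_E, tolerance = (1 / 64) / wmx$sigma_E)
  }

  # input narrower than recurrent connectivity: balance refused
  stn <- build_stimulus(stimulus_spec(sigma_X = 0.06), c(64, 64, 16))
  expect_error(spatial_balanced_rates(kern, stn),
               class = "imbalnet_infeasible")
})

test_that("corrected rates approach the balanced limit for feasible input", {
  st <- build_stimulus(stimulus_spec(sigma_X = 0.2), c(32, 32, 8))
  bal <- spatial_balanced_rates(kern, st)
  errs <- vapply(10^-(3:5), function(e) {
    sol <- spatial_corrected_rates(kern, st, epsilon = e, gain = 15)
    max(abs(sol$rE - bal$rE))
  }, numeric(1))
  # pointwise convergence: monotone decay, an order of magnitude over two
  # decades (nonuniform over modes, so slower than the discrete case)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 10)
})

test_that("narrow stimuli produce amplification with surround suppression", {
  broad <- spatial_corrected_rates(kern,
    build_stimulus(stimulus_spec(sigma_X = 0.2), c(64, 64, 8)), gain = 15)
  narrow <- spatial_corrected_rates(kern,
    build_stimulus(stimulus_spec(sigma_X = 0.06), c(64, 64, 8)), gain = 15)
  ctr <- c(33, 33)
  profb <- apply(unclass(broad$rE), c(1, 2), mean)[, ctr[2]]
  profn <- apply(unclass(narrow$rE), c(1, 2), mean)[, ctr[2]]
  # center peak higher under the narrower (weaker total) input
  expect_gt(profn[ctr[1]], profb[ctr[1]])
  # flanking values dip below the broad-stimulus baseline: suppression
  flank <- c(ctr[1] - 12, ctr[1] + 12)
  expect_true(all(profn[flank] < profb[flank]))
})

test_that("size tuning and edge sharpness behave as the filter theory predicts", {
  sx <- seq(0.02, 0.3, by = 0.04)
  scan <- size_tuning_scan(kern, sx, gain = 15)
  # broad lateral excitation (alpha_E > alpha_X): one interior maximum
  expect_length(scan$maxima_E, 1)
  # local inhibition (alpha_I = alpha_X): monotone increasing
  expect_length(scan$maxima_I, 0)
  expect_true(all(diff(scan$curve$rI) > 0))

  # sharpness index basics
  expect_equal(sharpness_index(rep(3, 10)), 0)
  step <- c(rep(0, 8), rep(1, 8))
  expect_equal(sharpness_index(step), 16)
})
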