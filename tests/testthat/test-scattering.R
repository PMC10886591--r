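wl_grid <- seq(500, 800, by = 10)

test_that("forward model obeys the lambda^-3 law and linearity in mu", {
  cst <- scattering_constants()
  tau0 <- forward_turbidity(5e12, 0, 1e-3, c(500, 800), cst)
  expect_equal(tau0[1] / tau0[2], (800 / 500)^3)

  tau1 <- forward_turbidity(5e12, 50, 1e-3, wl_grid, cst)
  tau2 <- forward_turbidity(1e13, 50, 1e-3, wl_grid, cst)
  expect_equal(tau2, 2 * tau1)

  # point-wise oracle re-evaluation of the formula
  oracle <- vapply(wl_grid, function(l) oracle_tau_single(5e12, 50, 1e-3, l),
                   numeric(1))
  expect_equal(tau1, oracle, tolerance = 1e-12)

  expect_error(forward_turbidity(5e12, 200, 1e-3, wl_grid, cst),
               "rigid-rod", class = "cq_model_domain")
})

test_that("Yeromonahos inversion is an exact round trip on noiseless spectra", {
  for (cst in list(scattering_constants(),
                   scattering_constants(n_s = 1.35, dndc = 0.19,
                                        k2_yeromonahos = 8,
                                        k2_carr_hermans = 8),
                   scattering_constants(wavelength_convention = "vacuum",
                                        k2_yeromonahos = 21,
                                        k2_carr_hermans = 21))) {
    tau <- forward_turbidity(5e12, 50, 1e-3, wl_grid, cst)
    fit <- suppressWarnings(fit_yeromonahos(wl_grid, tau, 1e-3, cst))
    expect_lt(abs(fit$mu - 5e12) / 5e12, 1e-3)
    expect_lt(abs(fit$diameter - 100) / 100, 1e-3)
  }

  # zero radius: mu recovered, radius unresolved or ~0
  cst <- scattering_constants()
  tau0 <- forward_turbidity(5e12, 0, 1e-3, wl_grid, cst)
  f0 <- suppressWarnings(fit_yeromonahos(wl_grid, tau0, 1e-3, cst))
  expect_lt(abs(f0$mu - 5e12) / 5e12, 1e-6)
  expect_true(!f0$radius_ok || abs(f0$radius) < 1)
})

test_that("noisy replicate spectra average to the true diameter", {
  set.seed(42)
  cst <- scattering_constants()
  scans <- simulate_scan(100, 1, cst, noise_sd = 0.01, replicates = 3,
                         background = 0.04, path_length = 0.3)
  ds <- vapply(scans, function(s) {
    x <- compute_path_length(s, 0.18)
    band <- s$wavelengths <= 800
    tau <- absorbance_to_turbidity(s$absorbance[band], 0.04, x)
    suppressWarnings(fit_yeromonahos(s$wavelengths[band], tau, 1e-3,
                                     cst))$diameter
  }, numeric(1))
  expect_gt(stats::sd(ds), 0)              # per-replicate estimates differ
  expect_lt(abs(mean(ds) - 100) / 100, 0.05)
})

test_that("Carr-Hermans bounds Yeromonahos from above and agrees for thin fibers", {
  cst <- scattering_constants()
  for (r in c(10, 30, 50, 80, 120)) {
    tau <- forward_turbidity(5e12, r, 1e-3, wl_grid, cst)
    dy <- suppressWarnings(fit_yeromonahos(wl_grid, tau, 1e-3, cst))$diameter
    dc <- suppressWarnings(fit_carr_hermans(wl_grid, tau, 1e-3, cst))$diameter
    expect_gte(dc, dy - 1e-9)
  }
  tau5 <- forward_turbidity(5e12, 5, 1e-3, wl_grid, cst)
  f5 <- suppressWarnings(fit_carr_hermans(wl_grid, tau5, 1e-3, cst))
  expect_lt(abs(f5$diameter - 10) / 10, 0.02)

  # doubling tau doubles mu and leaves the radius unchanged
  tau <- forward_turbidity(5e12, 50, 1e-3, wl_grid, cst)
  f1 <- suppressWarnings(fit_carr_hermans(wl_grid, tau, 1e-3, cst))
  f2 <- suppressWarnings(fit_carr_hermans(wl_grid, 2 * tau, 1e-3, cst))
  expect_equal(f2$mu, 2 * f1$mu, tolerance = 1e-9)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)
})

test_that("mu and radius estimates separate across a factorial sweep", {
  cst <- scattering_constants()
  for (mu in c(1e12, 1e13)) {
    ds <- c()
    for (r in c(10, 60, 120)) {
      tau <- forward_turbidity(mu, r, 1e-3, wl_grid, cst)
      f <- suppressWarnings(fit_yeromonahos(wl_grid, tau, 1e-3, cst))
      expect_lt(abs(f$mu - mu) / mu, 1e-6)         # mu invariant to r
      ds <- c(ds, f$diameter)
    }
    expect_equal(ds, 2 * c(10, 60, 120), tolerance = 1e-6) # r invariant to mu
  }
})

test_that("delta-method uncertainties vanish as noise vanishes", {
  cst <- scattering_constants()
  tau <- forward_turbidity(5e12, 50, 1e-3, wl_grid, cst)
  ses <- vapply(c(0.05, 0.01, 0), function(sdl) {
    set.seed(3)
    fac <- if (sdl > 0) rlnorm(length(tau), -sdl^2 / 2, sdl) else 1
    suppressWarnings(fit_yeromonahos(wl_grid, tau * fac, 1e-3,
                                     cst))$diameter_se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3], 1e-6)
})

test_that("method comparison reports per-method concentration slopes", {
  cst <- scattering_constants()
  est <- do.call(rbind, lapply(c(1, 2.7, 5), function(fib) {
    r <- 40 + 10 * fib                 # true diameter rising with fibrinogen
    tau <- forward_turbidity(1.2e9 * r^2, r, fib * 1e-3, wl_grid, cst)
    rbind(
      data.frame(level = fib, method = "yeromonahos",
                 diameter = suppressWarnings(
                   fit_yeromonahos(wl_grid, tau, fib * 1e-3, cst))$diameter),
      data.frame(level = fib, method = "carr_hermans",
                 diameter = suppressWarnings(
                   fit_carr_hermans(wl_grid, tau, fib * 1e-3, cst))$diameter))
  }))
  ref <- data.frame(level = c(1, 2.7, 5), diameter = 2 * (40 + 10 * c(1, 2.7, 5)))
  cm <- compare_methods(est, ref)
  expect_true(all(cm$slopes$slope > 0))
  sl <- setNames(cm$slopes$slope, cm$slopes$method)
  expect_gte(sl[["carr_hermans"]], sl[["yeromonahos"]])

  # identical spectra across conditions -> zero slopes
  flat <- data.frame(level = rep(c(1, 2, 3), each = 2),
                     method = rep(c("yeromonahos", "carr_hermans"), 3),
                     diameter = 100)
  cm0 <- compare_methods(flat)
  expect_equal(cm0$slopes$slope, c(0, 0), tolerance = 1e-12)
})

test_that("optically dense spectra are flagged for multiple scattering", {
  expect_true(multiple_scattering_flag(c(1, 9), 0.3))
  expect_false(multiple_scattering_flag(c(1, 2), 0.3))
})
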