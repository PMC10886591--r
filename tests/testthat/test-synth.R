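test_that("noiseless structure equals the linear trend", {
  cf <- default_trend_coefficients()
  ref <- clot_condition("purified", 2.7, "thrombin", 0.1)
  st <- simulate_structure(ref, cf, noise = FALSE)
  anchors <- cf[cf$sample_type == "purified", ]
  for (p in anchors$parameter)
    expect_equal(st[[p]], anchors$anchor[anchors$parameter == p])

  # printed purified diameter slope: Fg 2.7 -> 5 adds 10.97 * 2.3 nm
  hi <- simulate_structure(clot_condition("purified", 5, "thrombin", 0.1),
                           cf, noise = FALSE)
  expect_equal(hi$diameter_nm - st$diameter_nm, 10.97 * 2.3)

  set.seed(77); a <- simulate_structure(ref, cf)
  set.seed(77); b <- simulate_structure(ref, cf)
  expect_identical(a, b)
})

test_that("simulated kinetics is the analytic logistic and round-trips", {
  tr <- simulate_kinetics(5.24, 6.88e-3, 155, noise_sd = 0)
  tau <- absorbance_to_turbidity(tr, 0.04, 0.3)
  expect_equal(tau$turbidity,
               oracle_logistic(tau$times, 5.24, 6.88e-3, 155),
               tolerance = 1e-12)
  k <- extract_kinetics(tau)
  expect_lt(abs(k$max_turbidity_cm - 5.24) / 5.24, 0.01)
  expect_lt(abs(k$rate_cm_s - 6.88e-3) / 6.88e-3, 0.02)
  expect_lt(abs(k$lag_s - 155), 15)

  early <- simulate_kinetics(3.5, 1.5e-3, -40, noise_sd = 0)
  ke <- extract_kinetics(absorbance_to_turbidity(early, 0.04, 0.3))
  expect_true(ke$lag_censored)
})

test_that("simulated scans invert back to the generating diameter", {
  cst <- scattering_constants()
  sc <- simulate_scan(100, 2.7, cst, noise_sd = 0, replicates = 1)[[1]]
  expect_equal(compute_path_length(sc, 0.18), 0.3, tolerance = 1e-12)
  band <- sc$wavelengths <= 800
  tau <- absorbance_to_turbidity(sc$absorbance[band], 0.04, 0.3)
  fit <- suppressWarnings(fit_yeromonahos(sc$wavelengths[band], tau,
                                          2.7e-3, cst))
  expect_lt(abs(fit$diameter - 100) / 100, 0.005)
  expect_error(simulate_scan(500, 2.7, cst), class = "cq_model_domain")
})

test_that("network renderer hits its area target with exact bookkeeping", {
  set.seed(19)
  r <- render_network_image(0.25, 8, 130, size = 192, pixel_size = 0.05)
  expect_gte(r$achieved_area, 0.24)
  expect_lte(r$achieved_area, 0.27)
  expect_equal(r$achieved_area, mean(r$truth_mask))

  blank <- render_network_image(0.25, 8, 130, size = 64, pixel_size = 0.05,
                                n_segments = 0)
  expect_equal(mean(blank$truth_mask), 0)

  set.seed(4); i1 <- render_network_image(0.2, 6, 150, 96, 0.05)
  set.seed(4); i2 <- render_network_image(0.2, 6, 150, 96, 0.05)
  expect_identical(i1$image$pixels, i2$image$pixels)

  expect_error(render_network_image(0.5, 8, 130, 64, pixel_size = 0.5),
               class = "cq_pixel_too_coarse")
  expect_error(render_network_image(0.95, 8, 130, 64, 0.05),
               class = "cq_bad_target")
})

test_that("a full simulated study is deterministic and well-formed", {
  set.seed(123)
  ds1 <- simulate_study(replicates = 2, sample_types = "purified",
                        fibrinogen = c(1, 2.7), thrombin = c(0.1, 0.5))
  set.seed(123)
  ds2 <- simulate_study(replicates = 2, sample_types = "purified",
                        fibrinogen = c(1, 2.7), thrombin = c(0.1, 0.5))
  expect_identical(ds1$structure, ds2$structure)
  expect_identical(ds1$traces[[3]]$absorbance, ds2$traces[[3]]$absorbance)
  expect_equal(nrow(ds1$conditions), 8)
  expect_setequal(names(ds1$traces), ds1$conditions$well)

  dir <- withr::local_tempdir()
  p1 <- write_plate_files(ds1, file.path(dir, "a"))
  p2 <- write_plate_files(ds2, file.path(dir, "b"))
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
})

test_that("default study covers the full factorial grid", {
  set.seed(1)
  ds <- simulate_study(replicates = 1, sample_types = "purified")
  cond <- ds$conditions
  expect_setequal(unique(cond$fibrinogen_mg_ml), c(1, 2.7, 5, 10))
  expect_setequal(unique(cond$activator_level), c(0.1, 0.25, 0.5, 1))
  expect_equal(nrow(cond), 16)
})
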