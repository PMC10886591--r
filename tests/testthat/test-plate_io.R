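test_that("kinetic plate CSV round-trips through write and read", {
  dir <- withr::local_tempdir()
  # tiny wide export: wells A1, A2 at t = 0, 15, 30, 45 s
  wide <- data.frame(time_s = c(0, 15, 30, 45),
                     A1 = c(0.04, 0.05, 0.20, 0.50),
                     A2 = c(0.04, 0.041, 0.10, 0.30))
  f <- file.path(dir, "kin.csv")
  write.csv(wide, f, row.names = FALSE)
  layout <- data.frame(well = c("A1", "A2"), sample_type = "purified",
                       fibrinogen_mg_ml = 2.7, activator_kind = "thrombin",
                       activator_level = 0.1, replicate = c("r1", "r2"))
  plate <- read_kinetic_plate(f, layout)
  expect_length(plate, 2)
  expect_equal(plate[[1]]$trace$absorbance, wide$A1)
  expect_equal(plate[[2]]$trace$times, wide$time_s)
  expect_s3_class(plate[[1]]$condition, "clot_condition")

  # long format is accepted too
  long <- data.frame(time_s = rep(wide$time_s, 2),
                     well = rep(c("A1", "A2"), each = 4),
                     absorbance = c(wide$A1, wide$A2))
  f2 <- file.path(dir, "kin_long.csv")
  write.csv(long, f2, row.names = FALSE)
  plate2 <- read_kinetic_plate(f2, layout)
  expect_equal(plate2[[1]]$trace$absorbance, plate[[1]]$trace$absorbance)
})

test_that("simulated plate files read back bit-for-bit", {
  dir <- withr::local_tempdir()
  set.seed(11)
  ds <- simulate_study(replicates = 1, sample_types = "purified",
                       fibrinogen = c(1, 2.7), thrombin = 0.1)
  paths <- write_plate_files(ds, dir)
  layout <- read_condition_sheet(paths["conditions"])
  plate <- read_kinetic_plate(paths["kinetic"], layout)
  got <- setNames(lapply(plate, function(p) p$trace$absorbance),
                  vapply(plate, function(p) p$trace$well, ""))
  for (w in names(got)) expect_identical(got[[w]], ds$traces[[w]]$absorbance)
  scans <- read_wavelength_scans(paths["scans"])
  for (w in names(ds$scans))
    expect_identical(scans[[w]]$absorbance, ds$scans[[w]]$absorbance)
})

test_that("non-monotone time column and layout mismatches are rejected", {
  dir <- withr::local_tempdir()
  bad <- data.frame(time_s = c(0, 30, 15, 45), A1 = c(1, 2, 3, 4))
  f <- file.path(dir, "bad.csv")
  write.csv(bad, f, row.names = FALSE)
  layout <- data.frame(well = "A1", sample_type = "purified",
                       fibrinogen_mg_ml = 2.7, activator_kind = "thrombin",
                       activator_level = 0.1, replicate = "r1")
  expect_error(read_kinetic_plate(f, layout), "non-monotone time")

  good <- data.frame(time_s = c(0, 15), A1 = c(1, 2), A9 = c(1, 2))
  f2 <- file.path(dir, "good.csv")
  write.csv(good, f2, row.names = FALSE)
  layout2 <- rbind(layout, within(layout, well <- "B7"))
  expect_error(read_kinetic_plate(f2, layout2), "absent from file")
  expect_warning(read_kinetic_plate(f2, layout), "unmapped")
  expect_error(read_kinetic_plate(file.path(dir, "nope.csv"), layout),
               "missing file")
})

test_that("path length follows the 977-900 nm water step", {
  sc <- wavelength_scan(c(500, 900, 977), c(0.2, 0.10, 0.28))
  expect_equal(compute_path_length(sc, 0.18), 1.0)
  sc2 <- wavelength_scan(c(900, 977), c(0.10, 0.154))
  expect_equal(compute_path_length(sc2, 0.18), 0.30)
  expect_error(compute_path_length(wavelength_scan(c(900, 977), c(0.2, 0.2))),
               "A977 <= A900")
  expect_error(compute_path_length(wavelength_scan(c(500, 600), c(0.1, 0.2))),
               "900/977")
})

test_that("absorbance converts to turbidity as (A - bg) ln10 / x", {
  expect_equal(absorbance_to_turbidity(1.5, 0.5, 1.0), log(10))
  expect_equal(absorbance_to_turbidity(0.7, 0.2, 0.5), log(10))
  expect_equal(absorbance_to_turbidity(rep(0.3, 5), 0.3, 0.4), rep(0, 5))
  expect_error(absorbance_to_turbidity(1, 0, 0), "path")

  # linearity in A at fixed background/path, and path-doubling halves tau
  A1 <- runif(10); A2 <- runif(10)
  expect_equal(absorbance_to_turbidity(2 * A1 + 3 * A2, 0, 0.3),
               2 * absorbance_to_turbidity(A1, 0, 0.3) +
                 3 * absorbance_to_turbidity(A2, 0, 0.3))
  expect_equal(absorbance_to_turbidity(A1, 0, 0.6),
               absorbance_to_turbidity(A1, 0, 0.3) / 2)

  tr <- kinetic_trace(c(0, 15), c(0.14, 0.34), well = "A1")
  cv <- absorbance_to_turbidity(tr, 0.04, 0.5)
  expect_s3_class(cv, "turbidity_curve")
  expect_equal(cv$turbidity, c(0.1, 0.3) * log(10) / 0.5)
  expect_identical(cv$well, "A1")
})

test_that("condition invariants are enforced", {
  expect_error(clot_condition("purified", -1, "thrombin", 0.1), "fibrinogen")
  expect_error(clot_condition("purified", 2.7, "thrombin", -0.1), "activator")
  expect_error(clot_condition("purified", 3, "thrombin", 0.1,
                              validate_grid = TRUE), "off the study grid")
  ok <- clot_condition("plasma", 10, "tissue_factor", 75)
  expect_identical(ok$activator_kind, "tissue_factor")
})
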