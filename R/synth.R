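# Synthetic-data generator with known ground truth for every input stream:
# linear concentration -> structure/kinetics trends with Gaussian noise,
# rigid-rod scattering spectra with multiplicative noise, logistic clotting
# curves sampled every 15 s, rendered fiber-network images, and plate files.
# All randomness flows through R's RNG: seed once, get one dataset.

#' Default concentration-trend coefficients
#'
#' Per-parameter, per-sample-type linear model
#' `value = anchor + slope_fib * (Fg - 2.7) + slope_act * (Thr - 0.1)` with
#' Gaussian noise. Slopes are the printed simple-regression slopes of the
#' study the generator emulates (diameter from electron microscopy; pore,
#' percent area and fiber length from confocal morphometry; kinetic slopes
#' refit from the published per-concentration tables). Anchors are values at
#' the reference condition (2.7 mg/mL fibrinogen, 0.1 U/mL thrombin) —
#' kinetic anchors from the published tables, structural anchors chosen so
#' every parameter stays positive over the full factorial grid (synthetic
#' conveniences, not measured values). Noise SDs are calibrated so that the
#' default study supports coefficient recovery within 10% on per-condition
#' means with triplicate wells.
#'
#' @return data.frame: `parameter`, `sample_type`, `anchor`, `slope_fib`,
#'   `slope_act`, `noise_sd`.
#' @export
default_trend_coefficients <- function() {
  p <- function(parameter, anchor, slope_fib, slope_act, noise_sd)
    data.frame(parameter = parameter, sample_type = "purified",
               anchor = anchor, slope_fib = slope_fib, slope_act = slope_act,
               noise_sd = noise_sd, stringsAsFactors = FALSE)
  q <- function(parameter, anchor, slope_fib, slope_act, noise_sd) {
    d <- p(parameter, anchor, slope_fib, slope_act, noise_sd)
    d$sample_type <- "plasma"
    d
  }
  rbind(
    p("diameter_nm",       130,     10.97,   -90.4,   5),
    p("pore_um",            12,     -0.72,    -3.62,  0.15),
    p("percent_area",       20,      3.50,     8.42,  0.5),
    p("length_um",          12,     -0.64,    -4.08,  0.25),
    p("lag_s",             155,      7.73,  -186.7,   5),
    p("rate_cm_s",      6.88e-3,  0.674e-3, 26.2e-3,  5e-4),
    p("max_turbidity_cm", 5.24,     0.767,   -1.358,  0.15),
    q("diameter_nm",       250,     28.7,   -100.1,   5),
    q("pore_um",             8,     -0.24,    -3.58,  0.15),
    q("percent_area",       22,      0.96,    12.87,  0.5),
    q("length_um",          13,     -0.63,    -5.67,  0.25),
    q("lag_s",              45,    -14.7,   -228.9,   5),
    q("rate_cm_s",        39e-3,   4.64e-3, -0.886e-3, 5e-4),
    q("max_turbidity_cm", 4.16,     1.128,    1.100,  0.15)
  )
}

reference_condition <- c(fibrinogen = 2.7, activator = 0.1)

#' Simulate the measured structural/kinetic parameters of one clot
#'
#' Each parameter is its linear trend value plus Gaussian noise; the
#' noiseless truth is returned alongside. Parameters other than the lag
#' (whose negative values encode clotting before the first reading) are
#' clipped at a small positive floor with a warning if the trend drives
#' them non-positive.
#'
#' @param condition a [clot_condition()].
#' @param coeffs trend coefficients, see [default_trend_coefficients()].
#' @param noise add Gaussian noise (uses the current RNG state).
#' @return one-row data.frame with measured columns (`diameter_nm`, ...,
#'   `max_turbidity_cm`), matching `truth_*` columns and a `clipped` flag.
#' @export
simulate_structure <- function(condition, coeffs = default_trend_coefficients(),
                               noise = TRUE) {
  cf <- coeffs[coeffs$sample_type == condition$sample_type, ]
  dfib <- condition$fibrinogen - reference_condition[["fibrinogen"]]
  dact <- condition$activator_level - reference_condition[["activator"]]
  truth <- cf$anchor + cf$slope_fib * dfib + cf$slope_act * dact
  meas <- truth + if (noise) rnorm(nrow(cf), 0, cf$noise_sd) else 0
  clipped <- FALSE
  floor_at <- 1e-6
  not_lag <- cf$parameter != "lag_s"
  if (any(meas[not_lag] <= 0)) {
    warning("trend drove a parameter non-positive; clipped")
    meas[not_lag] <- pmax(meas[not_lag], floor_at)
    clipped <- TRUE
  }
  out <- as.data.frame(c(as.list(setNames(meas, cf$parameter)),
                         as.list(setNames(truth, paste0("truth_", cf$parameter)))))
  out$clipped <- clipped
  out
}

#' Simulate a logistic clotting trace
#'
#' The three clotting parameters map bijectively to a logistic
#' `tau(t) = baseline + P / (1 + exp(-k (t - t0)))` via `P = plateau -
#' baseline`, `k = 4 * max_rate / P`, `t0 = lag + 2/k` (the maximal-slope
#' tangent of the logistic intersects the baseline at `t0 - 2/k`). The curve
#' is emitted as absorbance for the given path length with additive Gaussian
#' read noise.
#'
#' @param plateau maximum turbidity, cm^-1.
#' @param max_rate maximal slope, cm^-1/s.
#' @param lag lag time, s (negative values start the clot before t = 0).
#' @param baseline baseline turbidity, cm^-1.
#' @param t_end,dt sampling span and interval, s.
#' @param noise_sd read noise on absorbance, OD.
#' @param path_length optical path length, cm.
#' @param background background OD added to the emitted absorbance.
#' @param well well label.
#' @return a [kinetic_trace()].
#' @export
simulate_kinetics <- function(plateau, max_rate, lag, baseline = 0,
                              t_end = 3600, dt = 15, noise_sd = 0.002,
                              path_length = 0.3, background = 0.04,
                              well = "") {
  stopifnot(plateau > baseline, baseline >= 0, max_rate > 0)
  P <- plateau - baseline
  k <- 4 * max_rate / P
  t0 <- lag + 2 / k
  if (t0 > t_end) warning("plateau not reached within the sampled window")
  times <- seq(0, t_end, by = dt)
  tau <- baseline + P / (1 + exp(-k * (times - t0)))
  A <- tau * path_length / log(10) + background +
    rnorm(length(times), 0, noise_sd)
  kinetic_trace(times, A, wavelength = 405, well = well,
                background = background)
}

#' Simulate end-point wavelength scans for one clot
#'
#' The fiber radius is half the diameter; the mass-length ratio follows the
#' homogeneous-cylinder coupling `mu = mu_per_nm2 * r^2` (protofibril count
#' scales with cross-sectional area) unless a fixed `mu` is given. The
#' rigid-rod spectrum is degraded with mean-one lognormal multiplicative
#' noise, converted to absorbance at the configured path length, and the
#' 900/977 nm water path-length rows are appended (fiber scattering at those
#' wavelengths is not modeled).
#'
#' @param diameter_nm fiber diameter, nm (> 0).
#' @param conc_mg_ml fibrinogen concentration, mg/mL (full conversion to
#'   fiber mass is assumed).
#' @param constants a [scattering_constants()].
#' @param noise_sd sdlog of the multiplicative noise (0 = noiseless).
#' @param replicates number of replicate scans.
#' @param path_length,background,k_water optics of the emitted absorbance.
#' @param mu_per_nm2 coupling of mass-length ratio to radius^2, Da/cm/nm^2.
#' @param mu fixed mass-length ratio overriding the coupling rule, Da/cm.
#' @param wavelengths analysis band, nm.
#' @param well_prefix labels become `<prefix>_s1`, ...
#' @return list of [wavelength_scan()] objects.
#' @export
simulate_scan <- function(diameter_nm, conc_mg_ml,
                          constants = scattering_constants(),
                          noise_sd = 0.01, replicates = 3,
                          path_length = 0.3, background = 0.04,
                          k_water = 0.18, mu_per_nm2 = 1.2e9, mu = NULL,
                          wavelengths = seq(500, 800, by = 10),
                          well_prefix = "well") {
  stopifnot(diameter_nm > 0, conc_mg_ml > 0)
  r <- diameter_nm / 2
  mu <- mu %||% (mu_per_nm2 * r^2)
  conc <- conc_mg_ml * 1e-3                     # mg/mL -> g/cm^3
  tau <- forward_turbidity(mu, r, conc, wavelengths, constants)
  w900 <- 0.10
  lapply(seq_len(replicates), function(i) {
    fac <- if (noise_sd > 0)
      rlnorm(length(tau), meanlog = -noise_sd^2 / 2, sdlog = noise_sd)
    else rep(1, length(tau))
    A <- tau * fac * path_length / log(10) + background
    wavelength_scan(c(wavelengths, 900, 977),
                    c(A, background + w900,
                      background + w900 + k_water * path_length),
                    well = sprintf("%s_s%d", well_prefix, i))
  })
}

# Rasterize a thick segment: TRUE for pixels within width/2 of the segment.
draw_segment <- function(mask, x0, y0, x1, y1, width) {
  nr <- nrow(mask); nc <- ncol(mask)
  half <- width / 2
  rlo <- max(1L, floor(min(x0, x1) - half)); rhi <- min(nr, ceiling(max(x0, x1) + half))
  clo <- max(1L, floor(min(y0, y1) - half)); chi <- min(nc, ceiling(max(y0, y1) + half))
  if (rlo > rhi || clo > chi) return(mask)
  rr <- rlo:rhi; cc <- clo:chi
  px <- matrix(rr, length(rr), length(cc))
  py <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  sub <- mask[rr, cc, drop = FALSE]
  sub[d2 <= half^2] <- TRUE
  mask[rr, cc] <- sub
  mask
}

#' Render a synthetic fiber-network image with ground truth
#'
#' Straight segments with length ~ the target fiber length and width ~ the
#' target diameter are drawn at random positions/orientations until the
#' drawn-area fraction reaches the target, then blurred (point-spread
#' emulation) and degraded with additive Gaussian noise. The exact truth
#' mask is returned.
#'
#' @param target_area area fraction to reach, in (0, 0.9).
#' @param fiber_length_um mean drawn segment length, um.
#' @param diameter_nm drawn fiber width, nm (must span >= 2 px).
#' @param size image side, pixels.
#' @param pixel_size um per pixel.
#' @param n_segments draw exactly this many segments instead of filling to
#'   the area target (0 gives a blank image).
#' @param blur_sigma Gaussian blur sigma, px.
#' @param noise_sd additive noise SD on the 0-255 intensity scale.
#' @param bg_level,fg_level background/foreground intensities (0-255).
#' @return list: `image` (a [network_image()], 0-255 intensities),
#'   `truth_mask` (logical), `achieved_area` (fraction).
#' @export
render_network_image <- function(target_area, fiber_length_um, diameter_nm,
                                 size = 256, pixel_size = 0.05,
                                 n_segments = NULL, blur_sigma = 0.5,
                                 noise_sd = 10, bg_level = 30,
                                 fg_level = 200) {
  if (is.null(n_segments) && (target_area <= 0 || target_area >= 0.9))
    abort_cq("target area fraction must be in (0, 0.9)", "cq_bad_target")
  width_px <- diameter_nm / 1000 / pixel_size
  if (width_px < 2)
    abort_cq(sprintf(
      "fiber width %.2f px < 2: use pixel_size <= %.3g um/px",
      width_px, diameter_nm / 2000), "cq_pixel_too_coarse")
  len_px <- fiber_length_um / pixel_size
  mask <- matrix(FALSE, size, size)
  drawn <- 0L
  budget <- if (is.null(n_segments))
    ceiling(50 * target_area * size^2 / (len_px * width_px)) else n_segments
  repeat {
    if (!is.null(n_segments) && drawn >= n_segments) break
    if (is.null(n_segments) && mean(mask) >= target_area) break
    if (drawn >= budget)
      if (is.null(n_segments))
        abort_cq(sprintf(
          "area target %.2f unreachable at this geometry; try a smaller pixel_size",
          target_area), "cq_unreachable_target")
      else break
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    th <- runif(1, 0, pi)
    L <- len_px * runif(1, 0.7, 1.3)
    mask <- draw_segment(mask, cx - L / 2 * cos(th), cy - L / 2 * sin(th),
                         cx + L / 2 * cos(th), cy + L / 2 * sin(th), width_px)
    drawn <- drawn + 1L
  }
  img <- bg_level + mask * (fg_level - bg_level)
  if (blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img / 255),
                                             sigma = blur_sigma)) * 255
  img <- img + rnorm(length(img), 0, noise_sd)
  img <- pmin(pmax(matrix(img, size, size), 0), 255)
  list(image = network_image(img, pixel_size), truth_mask = mask,
       achieved_area = mean(mask))
}

#' Simulate the default clot study
#'
#' Full factorial design — both sample types, the 4-level fibrinogen grid
#' crossed with the 4-level thrombin grid, triplicate wells — producing the
#' measured structural table, a logistic kinetic trace per well, and
#' rigid-rod wavelength scans per well. Wells whose fibers are too thick for
#' the rigid-rod model (correction term >= 1 in-band) get no scan and are
#' recorded under `scan_failures`.
#'
#' @param coeffs trend coefficients.
#' @param replicates wells per condition.
#' @param sample_types subset of `c("purified", "plasma")`.
#' @param fibrinogen,thrombin concentration grids.
#' @param noise logical: generate with the default noise model (set `FALSE`
#'   for noiseless ground-truth checks).
#' @param constants scattering constants.
#' @param path_length,background,k_water plate optics.
#' @param t_end,dt kinetic sampling.
#' @return list of class `clot_dataset`: `conditions` (data.frame),
#'   `structure` (measured + truth), `traces`, `scans` (named lists),
#'   `scan_failures` (data.frame), `optics` (list).
#' @export
simulate_study <- function(coeffs = default_trend_coefficients(),
                           replicates = 3,
                           sample_types = c("purified", "plasma"),
                           fibrinogen = fibrinogen_grid,
                           thrombin = thrombin_grid, noise = TRUE,
                           constants = scattering_constants(),
                           path_length = 0.3, background = 0.04,
                           k_water = 0.18, t_end = 3600, dt = 15) {
  design <- expand.grid(sample_type = sample_types,
                        fibrinogen_mg_ml = fibrinogen,
                        activator_level = thrombin,
                        replicate = paste0("r", seq_len(replicates)),
                        stringsAsFactors = FALSE)
  design <- design[order(design$sample_type, design$fibrinogen_mg_ml,
                         design$activator_level, design$replicate), ]
  design$well <- sprintf("W%03d", seq_len(nrow(design)))
  design$activator_kind <- "thrombin"
  conditions <- design[c("well", "sample_type", "fibrinogen_mg_ml",
                         "activator_kind", "activator_level", "replicate")]

  structure_rows <- list()
  traces <- list()
  scans <- list()
  fails <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- clot_condition(conditions$sample_type[i],
                           conditions$fibrinogen_mg_ml[i],
                           conditions$activator_kind[i],
                           conditions$activator_level[i],
                           conditions$replicate[i])
    w <- conditions$well[i]
    st <- suppressWarnings(simulate_structure(cond, coeffs, noise = noise))
    st$well <- w
    structure_rows[[w]] <- st
    traces[[w]] <- simulate_kinetics(
      plateau = st$max_turbidity_cm, max_rate = st$rate_cm_s,
      lag = st$lag_s, t_end = t_end, dt = dt,
      noise_sd = if (noise) 0.002 else 0, path_length = path_length,
      background = background, well = w)
    sc <- tryCatch(
      simulate_scan(st$diameter_nm, cond$fibrinogen, constants,
                    noise_sd = if (noise) 0.01 else 0, replicates = 1,
                    path_length = path_length, background = background,
                    k_water = k_water, well_prefix = w)[[1]],
      cq_model_domain = function(e) e)
    if (inherits(sc, "condition")) {
      fails[[w]] <- data.frame(well = w, reason = conditionMessage(sc),
                               stringsAsFactors = FALSE)
    } else {
      sc$well <- w
      scans[[w]] <- sc
    }
  }
  structure(list(conditions = conditions,
                 structure = do.call(rbind, structure_rows),
                 traces = traces, scans = scans,
                 scan_failures = if (length(fails)) do.call(rbind, fails)
                                 else data.frame(well = character(0),
                                                 reason = character(0)),
                 optics = list(path_length = path_length,
                               background = background, k_water = k_water)),
            class = "clot_dataset")
}

#' Write a simulated study to plate files
#'
#' Emits the files the ingestion layer reads: `conditions.csv`,
#' `kinetic.csv` (wide: `time_s` + one column per well), `scans.csv` (long:
#' `well`, `wavelength_nm`, `absorbance`, including a `BLANK` well carrying
#' the background spectrum and water path-length rows), and
#' `structure.csv` (the measured morphometry table). Values round-trip
#' losslessly (full double precision).
#'
#' @param dataset a `clot_dataset` from [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_plate_files <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(conditions = file.path(out_dir, "conditions.csv"),
             kinetic = file.path(out_dir, "kinetic.csv"),
             scans = file.path(out_dir, "scans.csv"),
             structure = file.path(out_dir, "structure.csv"))
  write.csv(dataset$conditions, paths["conditions"], row.names = FALSE)

  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.17g", col) else col)
    df
  }
  times <- dataset$traces[[1]]$times
  wide <- data.frame(time_s = times)
  for (w in names(dataset$traces)) wide[[w]] <- dataset$traces[[w]]$absorbance
  utils::write.table(fmt(wide), paths["kinetic"], sep = ",",
                     row.names = FALSE, quote = FALSE)

  long <- do.call(rbind, c(
    lapply(dataset$scans, function(s)
      data.frame(well = s$well, wavelength_nm = s$wavelengths,
                 absorbance = s$absorbance)),
    list(data.frame(well = "BLANK",
                    wavelength_nm = c(seq(500, 800, 10), 900, 977),
                    absorbance = c(rep(dataset$optics$background, 31),
                                   dataset$optics$background + 0.10,
                                   dataset$optics$background + 0.10 +
                                     dataset$optics$k_water *
                                     dataset$optics$path_length)))))
  utils::write.table(fmt(long), paths["scans"], sep = ",",
                     row.names = FALSE, quote = FALSE)

  write.csv(dataset$structure, paths["structure"], row.names = FALSE)
  invisible(paths)
}
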