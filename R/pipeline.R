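# Orchestration: ingestion -> kinetics -> scattering -> trends in one
# configured, seeded, logged run with table/JSON outputs.

#' Build a run configuration
#'
#' Either `input` (paths to `conditions`, `kinetic`, `scans`, `structure`
#' CSV files) is supplied, or the run simulates the default study, writes
#' its plate files under `out_dir/data` and ingests them back through the
#' same readers.
#'
#' @param out_dir output directory.
#' @param seed RNG seed recorded in the manifest; all run randomness flows
#'   from it.
#' @param input optional named list of input file paths.
#' @param replicates,sample_types,fibrinogen,thrombin,coeffs simulated-study
#'   design (ignored when `input` is given).
#' @param constants scattering constants registry.
#' @param lag_method,smooth_window,rate_window,threshold kinetics settings.
#' @param k_water water path-length constant, cm^-1.
#' @param alpha Grubbs screening level.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, input = NULL, replicates = 3,
                       sample_types = c("purified", "plasma"),
                       fibrinogen = fibrinogen_grid,
                       thrombin = thrombin_grid,
                       coeffs = default_trend_coefficients(),
                       constants = scattering_constants(),
                       lag_method = "tangent", smooth_window = 5L,
                       rate_window = 5L, threshold = 0.05, k_water = 0.18,
                       alpha = 0.05) {
  structure(list(out_dir = out_dir, seed = seed, input = input,
                 replicates = replicates, sample_types = sample_types,
                 fibrinogen = fibrinogen, thrombin = thrombin,
                 coeffs = coeffs, constants = constants,
                 lag_method = lag_method, smooth_window = smooth_window,
                 rate_window = rate_window, threshold = threshold,
                 k_water = k_water, alpha = alpha),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Diagnostics only — never throws. Reports missing fields, missing input
#' files, activator-unit mixing within a regression design, and
#' concentrations off the declared study grid.
#'
#' @param config a [run_config()] (or any list shaped like one).
#' @return character vector of diagnostics (empty when clean).
#' @export
validate_run_config <- function(config) {
  notes <- character(0)
  for (f in c("out_dir", "seed"))
    if (is.null(config[[f]])) notes <- c(notes, paste("missing field:", f))
  if (!is.null(config$input)) {
    for (nm in names(config$input))
      if (!file.exists(config$input[[nm]]))
        notes <- c(notes, paste("missing input file:", config$input[[nm]]))
    if (!is.null(config$input$conditions) &&
        file.exists(config$input$conditions)) {
      sheet <- tryCatch(read_condition_sheet(config$input$conditions),
                        error = function(e) NULL)
      if (is.null(sheet)) {
        notes <- c(notes, "condition sheet unreadable or invalid")
      } else {
        for (st in unique(sheet$sample_type)) {
          kinds <- unique(sheet$activator_kind[sheet$sample_type == st])
          if (length(kinds) > 1)
            notes <- c(notes, paste0(
              "mixed activator kinds in one design (", st, "): wells ",
              paste(sheet$well[sheet$sample_type == st], collapse = ",")))
        }
        off <- !vapply(sheet$fibrinogen_mg_ml, function(v)
          any(abs(v - fibrinogen_grid) < 1e-9), logical(1))
        if (any(off))
          notes <- c(notes, paste("off-grid fibrinogen in wells:",
                                  paste(sheet$well[off], collapse = ",")))
      }
    }
  }
  notes
}

kinetics_summary_table <- function(kin) {
  groups <- split(kin, list(kin$sample_type, kin$fibrinogen, kin$activator),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    cens <- mean(g$lag_censored) > 0.5
    lag_ok <- g$lag_s[!g$lag_censored & !g$lag_undefined]
    data.frame(
      sample_type = g$sample_type[1], fibrinogen = g$fibrinogen[1],
      activator = g$activator[1], n = nrow(g),
      lag_display = if (cens || !length(lag_ok)) "—" else
        sprintf("%.0f ± %.0f", mean(lag_ok), sd(lag_ok)),
      lag_mean_s = if (cens || !length(lag_ok)) NA_real_ else mean(lag_ok),
      rate_mean_e3 = mean(g$rate_cm_s) * 1e3,     # display scaling x10^-3
      rate_sd_e3 = sd(g$rate_cm_s) * 1e3,
      max_turbidity_mean = mean(g$max_turbidity_cm),
      max_turbidity_sd = sd(g$max_turbidity_cm),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_type, out$activator, out$fibrinogen), ]
  rownames(out) <- NULL
  out
}

grubbs_screen <- function(df, response, alpha) {
  keep <- rep(TRUE, nrow(df))
  for (g in split(seq_len(nrow(df)),
                  list(df$sample_type, df$fibrinogen, df$activator),
                  drop = TRUE)) {
    v <- df[[response]][g]
    ok <- is.finite(v)
    if (sum(ok) >= 3) {
      res <- grubbs_filter(v[ok], alpha)
      if (length(res$removed))
        keep[g[ok][v[ok] %in% res$removed]] <- FALSE
    }
  }
  keep
}

#' Run the full clot-characterization pipeline
#'
#' Simulates (or ingests) the study, extracts per-well clotting kinetics,
#' inverts the wavelength scans with both turbidimetric methods, screens
#' outliers per condition with the Grubbs test, fits per-sample-type
#' multiple regressions of every parameter on fibrinogen and activator
#' concentration, and writes the report bundle: `kinetics_table.csv`,
#' `diameter_methods.csv`, `structure_metrics.csv`,
#' `regression_models.json`, `sign_trends.csv`, `run_log.csv` and
#' `manifest.json`. Per-well failures are logged and the run completes with
#' partial outputs (`status = 2`) instead of aborting.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the tables, models, sign table, log and
#'   `status` (0 clean, 2 partial failures).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list()
  note <- function(stage, message)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, message = message,
                                           stringsAsFactors = FALSE)
  failures <- 0L

  # --- ingest -------------------------------------------------------------
  if (is.null(config$input)) {
    dataset <- simulate_study(coeffs = config$coeffs,
                              replicates = config$replicates,
                              sample_types = config$sample_types,
                              fibrinogen = config$fibrinogen,
                              thrombin = config$thrombin,
                              constants = config$constants,
                              k_water = config$k_water)
    paths <- write_plate_files(dataset, file.path(config$out_dir, "data"))
    if (nrow(dataset$scan_failures)) {
      failures <- failures + nrow(dataset$scan_failures)
      note("simulate", sprintf(
        "%d wells outside the rigid-rod domain (no scan generated)",
        nrow(dataset$scan_failures)))
    }
    input <- as.list(paths)
  } else input <- config$input

  layout <- read_condition_sheet(input$conditions)
  plate <- read_kinetic_plate(input$kinetic, layout)
  scans <- read_wavelength_scans(input$scans)
  structure_tab <- read_delim_sniffed(input$structure)
  note("ingest", sprintf("%d wells read, %d scans, %d structure rows",
                         length(plate), length(scans), nrow(structure_tab)))

  blank <- scans[["BLANK"]]
  sample_scans <- scans[setdiff(names(scans), "BLANK")]

  # --- kinetics -----------------------------------------------------------
  kin_rows <- lapply(plate, function(entry) {
    tr <- entry$trace
    x <- if (!is.null(sample_scans[[tr$well]]))
      compute_path_length(sample_scans[[tr$well]], config$k_water)
    else compute_path_length(blank, config$k_water)
    # Prefer the blank well's in-band absorbance as the kinetic background:
    # a logistic clot is already above baseline at the first read, so
    # per-well initial readings over-subtract.
    bg <- if (!is.null(blank)) mean(blank$absorbance[blank$wavelengths <= 800])
          else kinetic_background(tr)
    curve <- absorbance_to_turbidity(tr, bg, x)
    k <- extract_kinetics(curve, config$smooth_window, config$rate_window,
                          config$lag_method, config$threshold)
    k$sample_type <- entry$condition$sample_type
    k$fibrinogen <- entry$condition$fibrinogen
    k$activator <- entry$condition$activator_level
    k
  })
  kin <- do.call(rbind, kin_rows)
  note("kinetics", sprintf("%d wells, %d censored lags, %d undefined",
                           nrow(kin), sum(kin$lag_censored),
                           sum(kin$lag_undefined)))

  # --- scattering ---------------------------------------------------------
  fit_rows <- list()
  for (w in names(sample_scans)) {
    sc <- sample_scans[[w]]
    cond <- layout[layout$well == w, ]
    if (!nrow(cond)) next
    x <- compute_path_length(sc, config$k_water)
    band <- sc$wavelengths <= 800
    bg <- if (!is.null(blank)) blank$absorbance[match(sc$wavelengths[band],
                                                      blank$wavelengths)]
          else 0
    tau <- absorbance_to_turbidity(sc$absorbance[band], bg, x)
    conc <- cond$fibrinogen_mg_ml[1] * 1e-3
    for (f in list(fit_yeromonahos(sc$wavelengths[band], tau, conc,
                                   config$constants),
                   fit_carr_hermans(sc$wavelengths[band], tau, conc,
                                    config$constants))) {
      f$well <- w
      f$sample_type <- cond$sample_type[1]
      f$fibrinogen <- cond$fibrinogen_mg_ml[1]
      f$activator <- cond$activator_level[1]
      f$multiple_scattering <- multiple_scattering_flag(tau, x)
      fit_rows[[paste(w, f$method)]] <- f
    }
  }
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
  if (!is.null(fits)) {
    nf <- sum(fits$failed | !fits$radius_ok)
    if (nf) { failures <- failures + nf
              note("scattering", sprintf("%d fits without a resolvable radius", nf)) }
    note("scattering", sprintf("%d fits on %d wells", nrow(fits),
                               length(unique(fits$well))))
  }

  # --- diameter method comparison (vs fibrinogen at the reference
  #     activator level, per sample type) ----------------------------------
  cmp_rows <- list()
  if (!is.null(fits)) for (st in unique(fits$sample_type)) {
    sub <- fits[fits$sample_type == st &
                  abs(fits$activator - reference_condition[["activator"]]) <
                    1e-9 & fits$radius_ok, ]
    if (!nrow(sub)) next
    est <- data.frame(level = sub$fibrinogen, method = sub$method,
                      diameter = sub$diameter)
    ref_rows <- structure_tab[structure_tab$well %in%
                                layout$well[layout$sample_type == st &
                                              abs(layout$activator_level -
                                                    0.1) < 1e-9], ]
    ref <- data.frame(level = layout$fibrinogen_mg_ml[match(ref_rows$well,
                                                            layout$well)],
                      diameter = ref_rows$diameter_nm)
    cm <- compare_methods(est, ref)
    if (nrow(cm$slopes)) { cm$slopes$sample_type <- st
                           cmp_rows[[st]] <- cm$slopes }
  }
  cmp <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else data.frame()

  # --- trends -------------------------------------------------------------
  resp <- merge(structure_tab[c("well", "diameter_nm", "pore_um",
                                "percent_area", "length_um")],
                kin[c("well", "lag_s", "lag_censored", "lag_undefined",
                      "rate_cm_s", "max_turbidity_cm", "sample_type",
                      "fibrinogen", "activator")], by = "well")
  resp$lag_s[resp$lag_censored | resp$lag_undefined] <- NA_real_
  params <- c("diameter_nm", "pore_um", "percent_area", "length_um",
              "lag_s", "rate_cm_s", "max_turbidity_cm")
  models <- list()
  removed_total <- 0L
  for (st in unique(resp$sample_type)) {
    d <- resp[resp$sample_type == st, ]
    for (pm in params) {
      keep <- grubbs_screen(d, pm, config$alpha)
      removed_total <- removed_total + sum(!keep)
      m <- tryCatch(multiple_regression(d[keep, ], pm),
                    error = function(e) e)
      if (inherits(m, "error")) {
        failures <- failures + 1L
        note("trends", sprintf("%s/%s: %s — falling back to simple regression",
                               st, pm, conditionMessage(m)))
        axis <- if (length(unique(d$fibrinogen)) > 1) "fibrinogen"
                else "activator"
        sr <- tryCatch(simple_regression(d[[axis]][keep], d[[pm]][keep]),
                       error = function(e) NULL)
        if (!is.null(sr))
          models[[paste(st, pm)]] <- list(response = pm, sample_type = st,
                                          beta0 = sr$intercept,
                                          beta_fib = sr$slope,
                                          beta_act = NA_real_,
                                          r_squared = sr$r_squared,
                                          n = sr$n, simple_fallback = TRUE)
      } else {
        models[[paste(st, pm)]] <- c(list(sample_type = st),
                                     unclass(m)[c("response", "beta0",
                                                  "beta_fib", "beta_act",
                                                  "r_squared", "n")])
      }
    }
  }
  note("trends", sprintf("%d Grubbs removals, %d models fitted",
                         removed_total, length(models)))
  mdf <- do.call(rbind, lapply(models, function(m)
    data.frame(response = m$response, sample_type = m$sample_type,
               beta_fib = m$beta_fib,
               beta_act = if (is.null(m$beta_act) || is.na(m$beta_act)) 0
                          else m$beta_act,
               stringsAsFactors = FALSE)))
  signs <- sign_trend_table(mdf)

  # --- write bundle -------------------------------------------------------
  ktab <- kinetics_summary_table(kin)
  out <- function(f) file.path(config$out_dir, f)
  write.csv(ktab, out("kinetics_table.csv"), row.names = FALSE)
  write.csv(cmp, out("diameter_methods.csv"), row.names = FALSE)
  write.csv(structure_tab, out("structure_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(unname(models), out("regression_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(signs, out("sign_trends.csv"), row.names = FALSE)
  logdf <- do.call(rbind, log)
  write.csv(logdf, out("run_log.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(list(seed = config$seed,
                                    replicates = config$replicates,
                                    sample_types = config$sample_types,
                                    lag_method = config$lag_method,
                                    k_water = config$k_water,
                                    alpha = config$alpha),
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("clotquant")),
                   config_hash = unname(tools::md5sum(tf)),
                   wells = nrow(kin), status = if (failures) 2L else 0L)
  unlink(tf)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(kinetics = kin, kinetics_table = ktab, fits = fits,
                 method_comparison = cmp, models = models, signs = signs,
                 log = logdf, status = if (failures) 2L else 0L))
}
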