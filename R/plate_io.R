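# Plate ingestion: condition sheets, kinetic and spectral exports, optical
# path length, absorbance -> turbidity conversion.

#' Study concentration grids
#'
#' Fibrinogen and thrombin levels of the factorial study design
#' (fibrinogen 1-10 mg/mL; thrombin 0.1-1 U/mL). Used when condition
#' validation against the declared grid is requested.
#' @name study_grids
#' @keywords internal
NULL
fibrinogen_grid <- c(1, 2.7, 5, 10)     # mg/mL
thrombin_grid   <- c(0.1, 0.25, 0.5, 1) # U/mL

#' Construct a clot condition record
#'
#' A condition ties a well (or image) to its sample type, fibrinogen
#' concentration and clotting activator.
#'
#' @param sample_type `"purified"` (isolated fibrinogen + thrombin) or
#'   `"plasma"` (pooled plasma).
#' @param fibrinogen fibrinogen concentration, mg/mL (> 0).
#' @param activator_kind `"thrombin"` (U/mL) or `"tissue_factor"` (pM).
#' @param activator_level activator concentration in the units of its kind
#'   (>= 0).
#' @param replicate_id replicate label.
#' @param validate_grid if `TRUE`, require fibrinogen (and thrombin levels)
#'   to lie on the declared study grid.
#' @return A list of class `clot_condition`.
#' @export
clot_condition <- function(sample_type, fibrinogen, activator_kind,
                           activator_level, replicate_id = "r1",
                           validate_grid = FALSE) {
  sample_type <- match.arg(sample_type, c("purified", "plasma"))
  activator_kind <- match.arg(activator_kind, c("thrombin", "tissue_factor"))
  if (!is.finite(fibrinogen) || fibrinogen <= 0)
    abort_cq("fibrinogen concentration must be > 0 mg/mL", "cq_bad_condition")
  if (!is.finite(activator_level) || activator_level < 0)
    abort_cq("activator level must be >= 0", "cq_bad_condition")
  if (validate_grid) {
    if (!any(abs(fibrinogen - fibrinogen_grid) < 1e-9))
      abort_cq(sprintf("fibrinogen %g mg/mL is off the study grid {%s}",
                       fibrinogen, paste(fibrinogen_grid, collapse = ", ")),
               "cq_off_grid")
    if (activator_kind == "thrombin" &&
        !any(abs(activator_level - thrombin_grid) < 1e-9))
      abort_cq(sprintf("thrombin %g U/mL is off the study grid {%s}",
                       activator_level, paste(thrombin_grid, collapse = ", ")),
               "cq_off_grid")
  }
  structure(list(sample_type = sample_type, fibrinogen = fibrinogen,
                 activator_kind = activator_kind,
                 activator_level = activator_level,
                 replicate_id = as.character(replicate_id)),
            class = "clot_condition")
}

#' Construct a kinetic absorbance trace
#'
#' @param times acquisition times, seconds, strictly increasing.
#' @param absorbance optical density readings, same length as `times`.
#' @param wavelength acquisition wavelength, nm (405 by default).
#' @param well well label.
#' @param background optional background OD already known for the well.
#' @return A list of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, absorbance, wavelength = 405, well = "",
                          background = NA_real_) {
  if (length(times) != length(absorbance))
    abort_cq("times and absorbance must have equal length", "cq_bad_trace")
  if (length(times) && any(diff(times) <= 0))
    abort_cq("non-monotone time column", "cq_nonmonotone_time")
  structure(list(times = as.numeric(times),
                 absorbance = as.numeric(absorbance),
                 wavelength = wavelength, well = well,
                 background = background),
            class = "kinetic_trace")
}

#' Construct an end-point wavelength scan
#'
#' @param wavelengths wavelengths, nm, strictly increasing.
#' @param absorbance optical density at each wavelength.
#' @param well well label.
#' @return A list of class `wavelength_scan`.
#' @export
wavelength_scan <- function(wavelengths, absorbance, well = "") {
  if (length(wavelengths) != length(absorbance))
    abort_cq("wavelengths and absorbance must have equal length",
             "cq_bad_scan")
  o <- order(wavelengths)
  wavelengths <- as.numeric(wavelengths[o])
  absorbance <- as.numeric(absorbance[o])
  if (any(diff(wavelengths) <= 0))
    abort_cq("duplicate wavelength rows in scan", "cq_bad_scan")
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 well = well),
            class = "wavelength_scan")
}

#' Construct a turbidity curve
#'
#' Produced by [absorbance_to_turbidity()]; direct construction is exposed
#' for the simulator and tests.
#'
#' @param times seconds.
#' @param turbidity turbidity, cm^-1, finite.
#' @param path_length optical path length, cm (> 0).
#' @param well well label.
#' @return A list of class `turbidity_curve`.
#' @export
turbidity_curve <- function(times, turbidity, path_length, well = "") {
  if (!is.finite(path_length) || path_length <= 0)
    abort_cq("path_length must be > 0 cm", "cq_bad_path")
  if (any(!is.finite(turbidity)))
    abort_cq("turbidity must be finite", "cq_bad_curve")
  if (length(times) && any(diff(times) <= 0))
    abort_cq("non-monotone time column", "cq_nonmonotone_time")
  structure(list(times = as.numeric(times), turbidity = as.numeric(turbidity),
                 path_length = path_length, well = well),
            class = "turbidity_curve")
}

# Sniff the field delimiter of a delimited text file (decimal point assumed).
sniff_delim <- function(path) {
  line <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))))
  names(counts)[which.max(counts)]
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) abort_cq(paste("missing file:", path), "cq_missing_file")
  read.csv(path, sep = sniff_delim(path), check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Read a condition sheet
#'
#' Expected columns: `well`, `sample_type`, `fibrinogen_mg_ml`,
#' `activator_kind`, `activator_level`, `replicate`.
#'
#' @param path CSV file.
#' @param validate_grid validate concentrations against the study grid.
#' @return data.frame with one validated row per well.
#' @export
read_condition_sheet <- function(path, validate_grid = FALSE) {
  df <- read_delim_sniffed(path)
  need <- c("well", "sample_type", "fibrinogen_mg_ml", "activator_kind",
            "activator_level", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_cq(paste("condition sheet missing columns:",
                   paste(miss, collapse = ", ")), "cq_bad_sheet")
  for (i in seq_len(nrow(df)))
    clot_condition(df$sample_type[i], df$fibrinogen_mg_ml[i],
                   df$activator_kind[i], df$activator_level[i],
                   df$replicate[i], validate_grid = validate_grid)
  df
}

layout_condition <- function(layout, well) {
  row <- layout[layout$well == well, , drop = FALSE]
  clot_condition(row$sample_type[1], row$fibrinogen_mg_ml[1],
                 row$activator_kind[1], row$activator_level[1],
                 row$replicate[1])
}

#' Read a kinetic plate export
#'
#' Accepts a wide export (a time column followed by one column per well) or a
#' long export (columns `time_s`, `well`, `absorbance`). The delimiter is
#' sniffed; decimal point is required. Wells present in the file but absent
#' from the layout are skipped with a warning.
#'
#' @param path kinetic CSV.
#' @param layout condition sheet data.frame (see [read_condition_sheet()]).
#' @param wavelength acquisition wavelength recorded on each trace, nm.
#' @return list of `list(condition =, trace =)` entries, one per mapped well.
#' @export
read_kinetic_plate <- function(path, layout, wavelength = 405) {
  df <- read_delim_sniffed(path)
  if (all(c("time_s", "well", "absorbance") %in% names(df))) {
    wells_in_file <- unique(df$well)
    get_trace <- function(w) {
      sub <- df[df$well == w, ]
      kinetic_trace(sub$time_s, sub$absorbance, wavelength, well = w)
    }
  } else {
    tcol <- names(df)[1]
    wells_in_file <- setdiff(names(df), tcol)
    get_trace <- function(w)
      kinetic_trace(df[[tcol]], df[[w]], wavelength, well = w)
  }
  absent <- setdiff(layout$well, wells_in_file)
  if (length(absent))
    abort_cq(paste("layout wells absent from file:",
                   paste(absent, collapse = ", ")), "cq_layout_mismatch")
  unmapped <- setdiff(wells_in_file, layout$well)
  if (length(unmapped))
    warning("skipping unmapped wells: ", paste(unmapped, collapse = ", "))
  mapped <- intersect(wells_in_file, layout$well)
  lapply(mapped, function(w)
    list(condition = layout_condition(layout, w), trace = get_trace(w)))
}

#' Read end-point wavelength scans
#'
#' Accepts long (`well`, `wavelength_nm`, `absorbance`) or wide
#' (`wavelength_nm` column followed by one column per well) exports.
#'
#' @param path spectral CSV.
#' @return named list of [wavelength_scan()] objects (all wells, including
#'   any blank wells; condition mapping is left to the caller).
#' @export
read_wavelength_scans <- function(path) {
  df <- read_delim_sniffed(path)
  if (all(c("well", "wavelength_nm", "absorbance") %in% names(df))) {
    wells <- unique(df$well)
    out <- lapply(wells, function(w) {
      sub <- df[df$well == w, ]
      wavelength_scan(sub$wavelength_nm, sub$absorbance, well = w)
    })
  } else {
    wcol <- names(df)[1]
    wells <- setdiff(names(df), wcol)
    out <- lapply(wells, function(w)
      wavelength_scan(df[[wcol]], df[[w]], well = w))
  }
  setNames(out, wells)
}

#' Optical path length from the near-infrared water absorbance step
#'
#' The water absorbance difference between 977 nm and 900 nm is proportional
#' to the liquid column height, so `x = (A977 - A900) / k_water` converts the
#' measured step into the optical path length of the well.
#'
#' @param scan a [wavelength_scan()] containing 900 and 977 nm readings.
#' @param k_water water absorbance-difference constant per cm of path,
#'   cm^-1 (default 0.18, the standard near-IR differential used for
#'   microplate path-length correction; instrument-specific values can be
#'   supplied).
#' @return path length, cm.
#' @export
compute_path_length <- function(scan, k_water = 0.18) {
  stopifnot(inherits(scan, "wavelength_scan"), k_water > 0)
  a900 <- scan$absorbance[match(900, scan$wavelengths)]
  a977 <- scan$absorbance[match(977, scan$wavelengths)]
  if (is.na(a900) || is.na(a977))
    abort_cq("scan lacks the 900/977 nm path-length rows", "cq_no_path_rows")
  if (a977 <= a900)
    abort_cq("A977 <= A900: empty well or mis-assigned blank",
             "cq_bad_path_step")
  (a977 - a900) / k_water
}

#' Convert absorbance to turbidity
#'
#' Background-subtracted absorbance divided by the optical path length and
#' multiplied by ln(10): `tau_i = (A_i - background) * ln(10) / x`, giving
#' turbidity in cm^-1.
#'
#' @param x a numeric vector, [kinetic_trace()] or [wavelength_scan()].
#' @param background background OD to subtract (scalar or per-element).
#' @param path_length optical path length, cm (> 0).
#' @return numeric vector for numeric input; [turbidity_curve()] for a
#'   kinetic trace; `list(wavelengths, turbidity, well)` for a scan.
#' @export
absorbance_to_turbidity <- function(x, background = 0, path_length) {
  UseMethod("absorbance_to_turbidity")
}

#' @export
absorbance_to_turbidity.default <- function(x, background = 0, path_length) {
  if (!is.finite(path_length) || path_length <= 0)
    abort_cq("path_length must be > 0 cm", "cq_bad_path")
  (x - background) * log(10) / path_length
}

#' @export
absorbance_to_turbidity.kinetic_trace <- function(x, background = 0,
                                                  path_length) {
  tau <- absorbance_to_turbidity(x$absorbance, background, path_length)
  turbidity_curve(x$times, tau, path_length, well = x$well)
}

#' @export
absorbance_to_turbidity.wavelength_scan <- function(x, background = 0,
                                                    path_length) {
  list(wavelengths = x$wavelengths,
       turbidity = absorbance_to_turbidity(x$absorbance, background,
                                           path_length),
       well = x$well)
}

#' Default kinetic background estimate
#'
#' Mean of the first pre-lag readings of a trace; used when the layout does
#' not designate a blank well.
#'
#' @param trace a [kinetic_trace()].
#' @param n_points number of initial readings to average.
#' @return background OD.
#' @export
kinetic_background <- function(trace, n_points = 3L) {
  mean(head(trace$absorbance, n_points))
}
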