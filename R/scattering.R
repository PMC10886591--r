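# Rigid-rod wavelength-dependent turbidity and its two linearized
# inversions.
#
# Forward model: tau(lambda) = K1 * c * mu * lambda^-3 * (1 - K2 * r^2 / lambda^2)
# with K1 = (88/15) * pi^3 * n_s * (dn/dc)^2 / N_A. A suspension of long thin
# rigid rods scatters with a lambda^-3 turbidity; the K2 term is the
# first-order finite-radius correction. Two classic linearizations recover
# the mass-length ratio mu (Da/cm) and radius r:
#   Yeromonahos:  tau * lambda^5 = K1*c*mu * (lambda^2 - K2 r^2)  (exact line)
#   Carr-Hermans: c / (tau * lambda^3) = (1/(K1 mu)) * (1 + K2 r^2/lambda^2 + ...)
# The Carr-Hermans line truncates the geometric series, which inflates its
# fitted slope and hence its diameter relative to Yeromonahos.

#' Scattering constants registry
#'
#' Physical constants of the rigid-rod turbidity model. `K1` is always
#' derived as `(88/15) * pi^3 * n_s * (dn/dc)^2 / N_A`, never stored. The
#' per-method radius-correction coefficients default to `(184/154) * pi^2`;
#' published variants differ both in this coefficient and in whether the
#' model wavelength is the vacuum value or the in-medium value
#' (lambda / n_s), so both are configurable. The default convention is
#' `"vacuum"`, which keeps the finite-radius correction below 1 across the
#' full fiber-radius range of the study grid.
#'
#' @param n_s solvent refractive index (default 1.333, aqueous buffer).
#' @param dndc refractive index increment of fibrin, cm^3/g (default 0.186).
#' @param k2_carr_hermans,k2_yeromonahos radius-correction coefficients.
#' @param wavelength_convention `"vacuum"` (default) or `"in_medium"`
#'   (lambda_vac / n_s).
#' @return list of class `scattering_constants`.
#' @export
scattering_constants <- function(n_s = 1.333, dndc = 0.186,
                                 k2_carr_hermans = (184 / 154) * pi^2,
                                 k2_yeromonahos = (184 / 154) * pi^2,
                                 wavelength_convention = c("vacuum",
                                                           "in_medium")) {
  wavelength_convention <- match.arg(wavelength_convention)
  stopifnot(n_s > 0, dndc > 0, k2_carr_hermans > 0, k2_yeromonahos > 0)
  structure(list(n_s = n_s, dndc = dndc, N_A = 6.02214076e23,
                 k2_carr_hermans = k2_carr_hermans,
                 k2_yeromonahos = k2_yeromonahos,
                 wavelength_convention = wavelength_convention),
            class = "scattering_constants")
}

k1_constant <- function(constants) {
  (88 / 15) * pi^3 * constants$n_s * constants$dndc^2 / constants$N_A
}

k2_for <- function(constants, method) {
  switch(method, carr_hermans = constants$k2_carr_hermans,
         yeromonahos = constants$k2_yeromonahos)
}

# Wavelengths in cm under the configured convention.
lambda_cm <- function(wavelengths_nm, constants) {
  l <- wavelengths_nm * 1e-7
  if (constants$wavelength_convention == "in_medium") l <- l / constants$n_s
  l
}

#' Forward rigid-rod turbidity spectrum
#'
#' @param mu fiber mass-length ratio, Da/cm (> 0).
#' @param radius fiber radius, nm (>= 0).
#' @param conc fibrin mass concentration, g/cm^3 (> 0).
#' @param wavelengths wavelengths, nm (300-1000).
#' @param constants a [scattering_constants()] registry.
#' @param method whose K2 to use (the generator and the fit must agree);
#'   default `"yeromonahos"`.
#' @return turbidity at each wavelength, cm^-1.
#' @export
forward_turbidity <- function(mu, radius, conc, wavelengths,
                              constants = scattering_constants(),
                              method = "yeromonahos") {
  stopifnot(mu > 0, radius >= 0, conc > 0,
            all(wavelengths >= 300 & wavelengths <= 1000))
  l <- lambda_cm(wavelengths, constants)
  r_cm <- radius * 1e-7
  k2 <- k2_for(constants, method)
  u <- k2 * r_cm^2 / l^2
  if (any(u >= 1))
    abort_cq("K2 * r^2 / lambda^2 >= 1: fiber too thick for the rigid-rod model",
             "cq_model_domain")
  k1_constant(constants) * conc * mu * l^-3 * (1 - u)
}

fiber_estimate <- function(method, mu, mu_se, radius, radius_se, fit_r2,
                           radius_ok, failed = FALSE, note = "") {
  data.frame(method = method, mu = mu, mu_se = mu_se, radius = radius,
             radius_se = radius_se, diameter = 2 * radius,
             diameter_se = 2 * radius_se, fit_r2 = fit_r2,
             radius_ok = radius_ok, failed = failed, note = note,
             stringsAsFactors = FALSE)
}

fit_line <- function(x, y) {
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       V = vcov(fit), r2 = r2)
}

check_band <- function(wavelengths, tau) {
  keep <- wavelengths >= 500 & wavelengths <= 800
  if (sum(keep) < 3)
    abort_cq("need >= 3 wavelengths in the 500-800 nm band", "cq_short_band")
  if (any(tau[keep] <= 0))
    abort_cq("non-positive turbidity in the analysis band", "cq_bad_spectrum")
  keep
}

# Delta-method SE of r = sqrt(s) where s = r^2 has variance var_s.
radius_se_from <- function(s, var_s) {
  if (s <= 0 || var_s < 0) return(NA_real_)
  sqrt(var_s) / (2 * sqrt(s))
}

#' Yeromonahos inversion of a turbidity spectrum
#'
#' Fits the exact linearization `tau * lambda^5 = a * lambda^2 + b` over the
#' 500-800 nm band; then `mu = a / (K1 c)` and `r^2 = -b / (a K2)`.
#' Uncertainties are propagated from the fit covariance by the delta method.
#' Radii are reported in nm; a non-negative intercept yields a
#' radius-failure flag with `mu` still returned.
#'
#' @param wavelengths wavelengths, nm.
#' @param tau turbidity at each wavelength, cm^-1.
#' @param conc fibrin mass concentration, g/cm^3.
#' @param constants a [scattering_constants()] registry.
#' @return one-row data.frame (`FiberEstimate`): method, mu, radius,
#'   diameter (nm) with standard errors, fit R^2 and status flags.
#' @export
fit_yeromonahos <- function(wavelengths, tau, conc,
                            constants = scattering_constants()) {
  keep <- check_band(wavelengths, tau)
  l <- lambda_cm(wavelengths[keep], constants)
  y <- tau[keep] * l^5
  x <- l^2
  f <- fit_line(x, y)
  k1 <- k1_constant(constants)
  k2 <- k2_for(constants, "yeromonahos")
  if (f$slope <= 0)
    return(fiber_estimate("yeromonahos", NA_real_, NA_real_, NA_real_,
                          NA_real_, f$r2, FALSE, failed = TRUE,
                          note = "non-positive slope"))
  mu <- f$slope / (k1 * conc)
  mu_se <- sqrt(f$V[2, 2]) / (k1 * conc)
  s <- -f$intercept / (f$slope * k2)          # r^2, cm^2
  g <- c(-1 / (f$slope * k2),                 # ds/db
         f$intercept / (f$slope^2 * k2))      # ds/da
  var_s <- drop(t(g) %*% f$V %*% g)
  if (s <= 0)
    return(fiber_estimate("yeromonahos", mu, mu_se, NA_real_, NA_real_,
                          f$r2, FALSE, note = "no resolvable radius"))
  r_cm <- sqrt(s)
  fiber_estimate("yeromonahos", mu, mu_se, r_cm * 1e7,
                 radius_se_from(s, var_s) * 1e7, f$r2, TRUE)
}

#' Carr-Hermans inversion of a turbidity spectrum
#'
#' Fits `c / (tau * lambda^3) = p + q / lambda^2` over the 500-800 nm band;
#' then `mu = 1 / (K1 p)` and `r^2 = q / (p K2)`. Because the underlying
#' `(1 - u)^-1` series is truncated at first order, the fitted slope — and
#' hence the diameter — is inflated relative to the Yeromonahos inversion
#' for thick fibers.
#'
#' @inheritParams fit_yeromonahos
#' @return one-row data.frame (`FiberEstimate`), as [fit_yeromonahos()].
#' @export
fit_carr_hermans <- function(wavelengths, tau, conc,
                             constants = scattering_constants()) {
  keep <- check_band(wavelengths, tau)
  l <- lambda_cm(wavelengths[keep], constants)
  y <- conc / (tau[keep] * l^3)
  x <- 1 / l^2
  f <- fit_line(x, y)
  k1 <- k1_constant(constants)
  k2 <- k2_for(constants, "carr_hermans")
  p <- f$intercept; q <- f$slope
  if (p <= 0)
    return(fiber_estimate("carr_hermans", NA_real_, NA_real_, NA_real_,
                          NA_real_, f$r2, FALSE, failed = TRUE,
                          note = "non-positive intercept"))
  mu <- 1 / (k1 * p)
  mu_se <- sqrt(f$V[1, 1]) / (k1 * p^2)
  s <- q / (p * k2)                            # r^2, cm^2
  g <- c(-q / (p^2 * k2),                      # ds/dp
         1 / (p * k2))                         # ds/dq
  var_s <- drop(t(g) %*% f$V[c(1, 2), c(1, 2)] %*% g)
  if (s <= 0)
    return(fiber_estimate("carr_hermans", mu, mu_se, NA_real_, NA_real_,
                          f$r2, FALSE, note = "no resolvable radius"))
  r_cm <- sqrt(s)
  fiber_estimate("carr_hermans", mu, mu_se, r_cm * 1e7,
                 radius_se_from(s, var_s) * 1e7, f$r2, TRUE)
}

#' Flag spectra too optically dense for single-scattering analysis
#'
#' The rigid-rod inversion assumes single scattering; in-band absorbance
#' above 1 OD (tau * x > ln(10)) is flagged.
#'
#' @param tau in-band turbidity values, cm^-1.
#' @param path_length optical path length, cm.
#' @return logical flag.
#' @export
multiple_scattering_flag <- function(tau, path_length) {
  any(tau * path_length > log(10))
}

#' Compare diameter estimates across methods and conditions
#'
#' Builds the per-condition diameter table for both turbidimetric inversions
#' (plus an optional reference, e.g. microscopy-like ground truth) and the
#' per-method simple-regression slope of diameter versus concentration.
#'
#' @param estimates data.frame with columns `level` (the varied
#'   concentration), `method`, `diameter`.
#' @param reference optional data.frame with `level`, `diameter` for a
#'   reference technique; included as method `"reference"`.
#' @return list with `table` (mean diameter per level and method) and
#'   `slopes` (per-method slope, intercept, r_squared).
#' @export
compare_methods <- function(estimates, reference = NULL) {
  if (!is.null(reference)) {
    reference$method <- "reference"
    estimates <- rbind(estimates[c("level", "method", "diameter")],
                       reference[c("level", "method", "diameter")])
  }
  estimates <- estimates[is.finite(estimates$diameter), , drop = FALSE]
  if (!nrow(estimates))
    return(list(table = data.frame(), slopes = data.frame()))
  tab <- aggregate(diameter ~ level + method, estimates, mean)
  slopes <- do.call(rbind, lapply(split(tab, tab$method), function(d) {
    if (length(unique(d$level)) < 2)
      return(data.frame(method = d$method[1], slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_))
    f <- simple_regression(d$level, d$diameter)
    data.frame(method = d$method[1], slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared)
  }))
  rownames(slopes) <- NULL
  list(table = tab, slopes = slopes)
}
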