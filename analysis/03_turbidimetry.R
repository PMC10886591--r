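#!/usr/bin/env Rscript
# Step 3 — fiber diameters from multi-wavelength turbidity.
#
# Converts each end-point scan to a turbidity spectrum and inverts it with
# both rigid-rod linearizations (Carr-Hermans, Yeromonahos). Writes the
# per-well estimates and the per-method diameter-vs-fibrinogen slopes at
# the reference thrombin level, with the measured (microscopy-like)
# diameters as the reference method.

library(clotquant)

layout <- read_condition_sheet("results/data/conditions.csv")
scans <- read_wavelength_scans("results/data/scans.csv")
structure_tab <- read.csv("results/data/structure.csv")
blank <- scans[["BLANK"]]
cst <- scattering_constants()

rows <- list()
for (w in setdiff(names(scans), "BLANK")) {
  sc <- scans[[w]]
  cond <- layout[layout$well == w, ]
  x <- compute_path_length(sc)
  band <- sc$wavelengths <= 800
  bg <- blank$absorbance[match(sc$wavelengths[band], blank$wavelengths)]
  tau <- absorbance_to_turbidity(sc$absorbance[band], bg, x)
  conc <- cond$fibrinogen_mg_ml * 1e-3
  for (f in list(fit_yeromonahos(sc$wavelengths[band], tau, conc, cst),
                 fit_carr_hermans(sc$wavelengths[band], tau, conc, cst))) {
    f$well <- w
    f$sample_type <- cond$sample_type
    f$fibrinogen <- cond$fibrinogen_mg_ml
    f$activator <- cond$activator_level
    rows[[paste(w, f$method)]] <- f
  }
}
fits <- do.call(rbind, rows)
write.csv(fits, "results/diameters.csv", row.names = FALSE)
cat("Fitted", nrow(fits), "spectra;", sum(!fits$radius_ok),
    "without a resolvable radius.\n")

for (st in unique(fits$sample_type)) {
  sub <- fits[fits$sample_type == st & fits$activator == 0.1 & fits$radius_ok, ]
  if (!nrow(sub)) next
  wells <- layout$well[layout$sample_type == st & layout$activator_level == 0.1]
  refrows <- structure_tab[structure_tab$well %in% wells, ]
  ref <- data.frame(level = layout$fibrinogen_mg_ml[match(refrows$well,
                                                          layout$well)],
                    diameter = refrows$diameter_nm)
  cm <- compare_methods(data.frame(level = sub$fibrinogen,
                                   method = sub$method,
                                   diameter = sub$diameter), ref)
  cat("\n", st, "diameter slope vs fibrinogen (nm per mg/mL):\n")
  print(cm$slopes, row.names = FALSE)
  write.csv(cm$slopes, sprintf("results/diameter_slopes_%s.csv", st),
            row.names = FALSE)
}
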