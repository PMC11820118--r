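#!/usr/bin/env Rscript
# Stage 2: binodal analysis of the stage-1 dataset.
#
# Reads results/data/ and writes under results/binodal/:
#   - profile_plateaus.csv     coexisting densities per demo profile
#   - critical_points.csv      fitted (Tc, rho_c, d, A) per system
#   - delta_tc.csv             Tc change of every variant vs the wild type
#
# Run after analysis/01_simulate.R.

suppressPackageStartupMessages(library(pldscale))

data_dir <- "results/data"
out <- "results/binodal"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Coexisting densities from the demo slab profiles.
prof_files <- sort(list.files(file.path(data_dir, "profiles"),
                              full.names = TRUE))
plateaus <- do.call(rbind, lapply(prof_files, function(f) {
  ext <- extract_coexisting_densities(read_profile(f))
  data.frame(file = basename(f), rho_low = ext$rho_low,
             rho_high = ext$rho_high, err_low = ext$err_low,
             err_high = ext$err_high, coexistence = ext$coexistence)
}))
write.csv(plateaus, file.path(out, "profile_plateaus.csv"),
          row.names = FALSE)

## Critical-point fits for every binodal point set.
bin_files <- sort(list.files(file.path(data_dir, "binodals"),
                             pattern = "\\.csv$", full.names = TRUE))
fits <- list()
cp_rows <- NULL
for (f in bin_files) {
  id <- sub("\\.csv$", "", basename(f))
  tab <- read.csv(f)
  pts <- coexistence_points(tab$T_K, tab$rho_low, tab$rho_high,
                            tab$err_low, tab$err_high)
  cp <- fit_critical_point(pts)
  fits[[id]] <- cp
  cp_rows <- rbind(cp_rows, data.frame(
    system = id, Tc = cp$Tc, Tc_err = cp$Tc_err, rho_c = cp$rho_c,
    d = cp$d, A = cp$A))
}
write.csv(cp_rows, file.path(out, "critical_points.csv"),
          row.names = FALSE)

## Delta Tc of each variant against the wild type.
wt <- fits[["WT"]]
variant_ids <- setdiff(names(fits), "WT")
dtc <- do.call(rbind, lapply(variant_ids, function(v) {
  d <- delta_tc(fits[[v]], wt)
  data.frame(variant_id = v, delta_tc = d$value, delta_tc_err = d$error)
}))
write.csv(dtc, file.path(out, "delta_tc.csv"), row.names = FALSE)

message(sprintf("WT: Tc = %.2f +/- %.2f K, rho_c = %.4f g/cm^3",
                wt$Tc, wt$Tc_err, wt$rho_c))
message("wrote binodal results under ", out)
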