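#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dataset with known ground truth.
#
# Produces, under results/data/:
#   - profiles/T<temp>.csv        slab density profiles for a demo system
#   - binodals/<id>.csv           coexistence point sets (WT + R->K family)
#   - binodals/<id>.truth.json    the generating truth per system
#   - sequences.fasta             a synthetic PLD and designed variants
#   - variant_meta.csv            pair / N / L bookkeeping per variant
#
# Every output is a deterministic function of the seeds recorded here.

suppressPackageStartupMessages(library(pldscale))

out <- "results/data"
dir.create(file.path(out, "profiles"), recursive = TRUE,
           showWarnings = FALSE)
dir.create(file.path(out, "binodals"), recursive = TRUE,
           showWarnings = FALSE)

## Demo slab profiles at several temperatures: plateaus follow the
## closed-form binodal of the default truth, with fixed interface shape.
truth <- default_binodal_truth()
temps <- seq(320, 390, length.out = 10)
ref <- predict_binodal(truth, temps)
for (k in seq_along(temps)) {
  p <- synth_density_profile(rho_low = ref$rho_low[k],
                             rho_high = ref$rho_high[k],
                             noise_sd = 0.005, seed = 100L + k)
  write.csv(data.frame(z_A = p$z, rho_g_cm3 = p$rho, err = p$err),
            file.path(out, "profiles", sprintf("T%03d.csv", round(temps[k]))),
            row.names = FALSE)
}

## Coexistence point sets: a wild type plus an R->K variant family whose
## Tc shifts follow delta Tc = S * N / L with S = -1300 K.
fam <- list(
  list(id = "WT",  pair = NA,     N = 0L, L = 200L),
  list(id = "v01", pair = "R->K", N = 1L, L = 100L),
  list(id = "v02", pair = "R->K", N = 2L, L = 100L),
  list(id = "v03", pair = "R->K", N = 1L, L = 150L),
  list(id = "v04", pair = "R->K", N = 3L, L = 150L),
  list(id = "v05", pair = "R->K", N = 2L, L = 200L),
  list(id = "v06", pair = "R->K", N = 4L, L = 200L),
  list(id = "v07", pair = "R->K", N = 2L, L = 250L),
  list(id = "v08", pair = "R->K", N = 5L, L = 250L),
  list(id = "v09", pair = "R->K", N = 3L, L = 300L),
  list(id = "v10", pair = "R->K", N = 6L, L = 300L))
S_truth <- -1300
meta <- NULL
for (k in seq_along(fam)) {
  v <- fam[[k]]
  tr <- truth
  if (!is.na(v$pair)) tr$Tc <- truth$Tc + S_truth * v$N / v$L
  pts <- synth_coexistence_points(
    tr, temps = seq(320, tr$Tc - 10, length.out = 10),
    noise_sd = 0.002, seed = 200L + k)
  write.csv(as.data.frame(pts),
            file.path(out, "binodals", paste0(v$id, ".csv")),
            row.names = FALSE)
  write_truth(attr(pts, "truth"),
              file.path(out, "binodals", paste0(v$id, ".truth.json")))
  if (!is.na(v$pair)) {
    meta <- rbind(meta, data.frame(variant_id = v$id, pair = v$pair,
                                   N = v$N, L = v$L))
  }
}
write.csv(meta, file.path(out, "variant_meta.csv"), row.names = FALSE)

## A synthetic PLD plus designed point-mutation variants.
wt <- synth_pld_sequence(L = 200, seed = 42, id = "synthPLD")
variants <- list(
  design_variant(wt, mutation_spec("Y", "F", 4), seed = 1),
  design_variant(wt, mutation_spec("R", "K", 1), seed = 1),
  design_variant(wt, mutation_spec("Y", "X", 6), seed = 1))
write_fasta(c(list(wt), variants), file.path(out, "sequences.fasta"))

message("wrote synthetic dataset under ", out)
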