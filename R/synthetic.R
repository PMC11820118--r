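# Synthetic-data generators with known ground truth. The real dataset
# behind the scaling-law analysis is cluster-scale molecular dynamics
# (slab simulations of 140 sequence variants); these generators emulate
# the statistical shape of its observables — tanh-interface slab density
# profiles, binodal point sets obeying the coexistence and
# rectilinear-diameter laws, variant families following the scaling
# ansaetze with additive Gaussian noise, and PLD-like random sequences —
# so every pipeline stage can be exercised and validated against a known
# truth without any simulation. Every generator is a deterministic
# function of (truth, seed), and the truth serialises beside its output.

#' Default synthetic binodal truth
#'
#' Tc = 400 K, rho_c = 0.30 g/cm^3, d = 0.77, A = -0.001 g cm^-3 K^-1:
#' a fixture resembling typical PLD condensate phase diagrams (Tc of a few
#' hundred Kelvin, condensed densities below 1 g/cm^3), not values taken
#' from any specific system.
#'
#' @return list with `Tc`, `rho_c`, `d`, `A`.
#' @export
default_binodal_truth <- function() {
  list(Tc = 400, rho_c = 0.30, d = 0.77, A = -0.001)
}

#' Generate a slab density profile with known plateaus
#'
#' Double-tanh slab shape plus i.i.d. Gaussian noise:
#' `rho(z) = rho_low + (rho_high - rho_low)/2 *
#'   (tanh((z - z1)/w) - tanh((z - z2)/w)) + N(0, noise_sd)`.
#' Negative noisy densities are clipped at 0.
#'
#' @param rho_low,rho_high plateau densities (g/cm^3), `rho_high > rho_low`.
#' @param z1,z2 interface positions (Angstrom), `z1 < z2`.
#' @param w interface width (Angstrom).
#' @param box_z box length along the slab axis (Angstrom).
#' @param n_bins number of profile bins.
#' @param noise_sd Gaussian noise sd (g/cm^3).
#' @param seed integer seed.
#' @return a [density_profile()] with attribute `"truth"`.
#' @export
synth_density_profile <- function(rho_low = 0.05, rho_high = 0.60,
                                  z1 = 350, z2 = 650, w = 20,
                                  box_z = 1000, n_bins = 200,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(rho_high > rho_low, rho_low >= 0, z1 < z2, z2 < box_z)
  z <- (seq_len(n_bins) - 0.5) * box_z / n_bins
  rho <- rho_low + (rho_high - rho_low) / 2 *
    (tanh((z - z1) / w) - tanh((z - z2) / w))
  if (noise_sd > 0) {
    set.seed(seed)
    rho <- pmax(rho + stats::rnorm(n_bins, 0, noise_sd), 0)
  }
  out <- density_profile(z, rho,
                         err = if (noise_sd > 0) rep(noise_sd, n_bins)
                               else NULL)
  attr(out, "truth") <- list(rho_low = rho_low, rho_high = rho_high,
                             z1 = z1, z2 = z2, w = w, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate coexistence points from a known critical point
#'
#' Densities follow the closed-form binodal ([predict_binodal()]) with
#' additive Gaussian noise; the error columns are set to the noise sd.
#'
#' @param truth list with `Tc`, `rho_c`, `d`, `A`
#'   (see [default_binodal_truth()]).
#' @param temps temperature grid (Kelvin), all below `truth$Tc`.
#' @param noise_sd density noise sd (g/cm^3).
#' @param seed integer seed.
#' @return a [coexistence_points()] table with attribute `"truth"`.
#' @export
synth_coexistence_points <- function(truth = default_binodal_truth(),
                                     temps = seq(320, 390, length.out = 10),
                                     noise_sd = 0, seed = 1L) {
  if (any(temps >= truth$Tc)) {
    stop("temperature grid must lie below the true Tc = ", truth$Tc,
         call. = FALSE)
  }
  pts <- predict_binodal(truth, temps)
  if (noise_sd > 0) {
    set.seed(seed)
    pts$rho_low <- pts$rho_low + stats::rnorm(nrow(pts), 0, noise_sd)
    pts$rho_high <- pts$rho_high + stats::rnorm(nrow(pts), 0, noise_sd)
    pts$err_low <- noise_sd
    pts$err_high <- noise_sd
  }
  attr(pts, "truth") <- c(truth, list(noise_sd = noise_sd, seed = seed,
                                      temps = temps))
  pts
}

#' Generate a synthetic variant family under a scaling ansatz
#'
#' Observations follow `delta_tc = S_truth * x(ansatz) + N(0, noise_sd)`.
#' Counts `N` cycle over `n_range` and lengths over `lengths`, emulating a
#' family of variants of several PLDs with different mutation loads.
#'
#' @param pair mutation-pair label (e.g. `"R->K"`).
#' @param ansatz generating ansatz.
#' @param S_truth true scaling constant.
#' @param n_obs number of observations.
#' @param lengths protein lengths to cycle over.
#' @param n_range substitution counts to cycle over.
#' @param noise_sd Gaussian noise on delta Tc (Kelvin); the per-variant
#'   uncertainty column is set to this value.
#' @param seed integer seed.
#' @return a [variant_observations()] table with attribute `"truth"`.
#' @export
synth_variant_family <- function(pair = "R->K",
                                 ansatz = c("fraction", "count", "sqrt"),
                                 S_truth = -1300, n_obs = 20,
                                 lengths = c(100L, 150L, 200L, 250L, 300L),
                                 n_range = 1:10, noise_sd = 2, seed = 1L) {
  ansatz <- match.arg(ansatz)
  L <- rep_len(lengths, n_obs)
  N <- rep_len(n_range, n_obs)
  N <- pmin(N, L)
  x <- ansatz_x(N, L, ansatz)
  set.seed(seed)
  y <- S_truth * x + stats::rnorm(n_obs, 0, noise_sd)
  out <- variant_observations(
    variant_id = sprintf("synth_%s_%02d", gsub("[^A-Za-z]", "", pair),
                         seq_len(n_obs)),
    pair = pair, N = N, L = L, delta_tc = y, delta_tc_err = noise_sd)
  attr(out, "truth") <- list(pair = pair, ansatz = ansatz,
                             S_truth = S_truth, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Default composition targets for a synthetic PLD
#'
#' Class fractions inside the ranges observed across natural PLDs:
#' aromatics 0.25 (observed range roughly 0.19-0.43), charged 0.05 split
#' 0.03 positive / 0.02 negative (observed total 0.02-0.1), glycine 0.25,
#' Asn/Gln 0.20, remainder neutral spacers.
#'
#' @return named numeric vector over the six residue classes, summing to 1.
#' @export
default_pld_composition <- function() {
  c(aromatic = 0.25, positive = 0.03, negative = 0.02,
    neutral_pi = 0.20, glycine = 0.25, neutral = 0.25)
}

#' Generate a random PLD-like sequence with target composition
#'
#' Class counts are apportioned by largest-remainder rounding of the
#' target fractions; letters within each class are drawn uniformly from
#' the class members, and the whole sequence is shuffled.
#'
#' @param L sequence length (>= 20).
#' @param targets named class fractions summing to 1
#'   (see [default_pld_composition()]).
#' @param seed integer seed.
#' @param id sequence identifier.
#' @return a [pld_sequence()] with attribute `"truth"`.
#' @export
synth_pld_sequence <- function(L = 200L,
                               targets = default_pld_composition(),
                               seed = 1L, id = NULL) {
  stopifnot(L >= 20)
  targets <- targets[names(RESIDUE_CLASSES)]
  targets[is.na(targets)] <- 0
  names(targets) <- names(RESIDUE_CLASSES)
  if (any(targets < 0) || any(targets > 1) ||
      abs(sum(targets) - 1) > 1e-9) {
    stop("composition targets must be fractions in [0, 1] summing to 1",
         call. = FALSE)
  }
  quota <- L * targets
  counts <- floor(quota)
  rem <- quota - counts
  short <- L - sum(counts)
  if (short > 0) {
    ord <- order(-rem)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  set.seed(seed)
  letters_out <- unlist(lapply(names(counts), function(cl) {
    if (counts[[cl]] == 0) return(character(0))
    sample(RESIDUE_CLASSES[[cl]], counts[[cl]], replace = TRUE)
  }))
  letters_out <- sample(letters_out)
  out <- pld_sequence(if (is.null(id)) sprintf("synthPLD_L%d_s%d", L, seed)
                      else id,
                      letters_out)
  attr(out, "truth") <- list(L = L, targets = targets, seed = seed)
  out
}

#' Write a generator truth record beside an output file
#'
#' @param truth list (typically the `"truth"` attribute of a generator
#'   output).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
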