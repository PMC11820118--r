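# Independent oracles and small generators used across the suite.

AROMATIC_SET <- c("F", "W", "Y")
STICKER_SET <- c("F", "W", "Y", "K", "H", "R", "D", "E")

# Brute-force reimplementation of the aromatic patterning order parameter,
# written directly from the defining formulas with plain loops; kept
# independent of the package's segment bookkeeping.
sigma_aro_bruteforce <- function(residues, l) {
  L <- length(residues)
  n_aro <- sum(residues %in% AROMATIC_SET)
  sigma_t <- (2 * n_aro / L - 1)^2
  seg_sigma <- function(res) {
    starts <- seq(1, length(res), by = l)
    out <- numeric(0)
    for (s in starts) {
      seg <- res[s:min(s + l - 1, length(res))]
      li <- length(seg)
      na <- sum(seg %in% AROMATIC_SET)
      out <- c(out, ((2 * na / li - 1)^2 - sigma_t)^2)
    }
    out
  }
  ref <- c(rep("Y", n_aro), rep("A", L - n_aro))
  si <- seg_sigma(residues)
  smax <- seg_sigma(ref)
  total <- 0
  for (k in seq_along(si)) {
    if (smax[k] > 0) total <- total + si[k] / smax[k]
  }
  total * sum(residues %in% STICKER_SET) / L
}

random_residues <- function(L, p_aro = 0.3) {
  pool_aro <- AROMATIC_SET
  pool_other <- c("G", "S", "A", "N", "Q", "R", "K", "T", "P")
  n_aro <- rbinom(1, L, p_aro)
  sample(c(sample(pool_aro, n_aro, replace = TRUE),
           sample(pool_other, L - n_aro, replace = TRUE)))
}

# A clustered/dispersed pair with identical composition for window length
# l: L = n_win * l, with k aromatics in every window. The dispersed
# arrangement matches the global aromatic fraction in every window, so its
# per-window asymmetries (and hence sigma_aro) are exactly zero; the
# clustered one packs all aromatics at the head. Perfectly even dispersal
# is the regime where the clustered >= dispersed ordering is guaranteed:
# for uneven dispersal the per-window normalisation (which can be tiny at
# the reference's interface window) can invert the ordering.
matched_patterning_pair <- function(l, k, n_win = 8) {
  stopifnot(k >= 1, k <= l - 1)
  L <- n_win * l
  n_aro <- n_win * k
  aro <- sample(AROMATIC_SET, n_aro, replace = TRUE)
  rest <- sample(c("G", "S", "A", "N", "Q"), L - n_aro, replace = TRUE)
  clustered <- c(aro, rest)
  pos <- as.vector(outer(seq_len(k), (seq_len(n_win) - 1L) * l, "+"))
  dispersed <- character(L)
  dispersed[pos] <- aro
  dispersed[-pos] <- rest
  list(clustered = pld_sequence("clustered", clustered),
       dispersed = pld_sequence("dispersed", dispersed))
}

mini_params_path <- function() {
  system.file("extdata", "mpipi_params_mini.yaml", package = "pldscale")
}
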