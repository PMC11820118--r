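# Energy terms of the residue-level coarse-grained protein model used for
# the phase-separation simulations: one bead per amino acid, harmonic
# bonds, Debye-Hueckel screened electrostatics, and Wang-Frenkel pair
# interactions. Units package-wide: Angstrom, Kelvin, kcal/mol, elementary
# charges.

# Coulomb prefactor e^2 / (4 pi eps0) in kcal mol^-1 Angstrom e^-2
# (CODATA-derived).
COULOMB_KCAL <- 332.0637

# Model-wide defaults: bond force constant (kcal mol^-1 A^-2), equilibrium
# bond length (A), relative permittivity of water, inverse Debye screening
# length at 150 mM monovalent salt (A^-1).
MPIPI_GLOBALS <- list(k = 19.1, r0 = 3.81, eps_r = 80, kappa = 0.126)

#' Harmonic bond energy
#'
#' @param r bond length (Angstrom), vectorised.
#' @param k force constant (kcal mol^-1 A^-2).
#' @param r0 equilibrium bond length (Angstrom).
#' @return energy in kcal/mol.
#' @export
bond_energy <- function(r, k = MPIPI_GLOBALS$k, r0 = MPIPI_GLOBALS$r0) {
  stopifnot(all(r >= 0))
  0.5 * k * (r - r0)^2
}

#' Inverse Debye screening length
#'
#' Computes kappa = sqrt(2 e^2 N_A (1000 I) / (eps0 eps_r kB T)) in
#' Angstrom^-1 for a monovalent salt of ionic strength `ionic_strength`.
#' At 150 mM, eps_r = 80 and 300 K this gives 0.126 A^-1.
#'
#' @param ionic_strength mol/L (monovalent salt concentration).
#' @param eps_r relative permittivity (dimensionless).
#' @param T_K temperature in Kelvin.
#' @return kappa in Angstrom^-1.
#' @export
debye_kappa <- function(ionic_strength, eps_r = MPIPI_GLOBALS$eps_r,
                        T_K = 300) {
  stopifnot(ionic_strength >= 0, eps_r > 0, T_K > 0)
  e <- 1.602176634e-19      # C
  NA_ <- 6.02214076e23      # mol^-1
  eps0 <- 8.8541878128e-12  # F/m
  kB <- 1.380649e-23        # J/K
  kappa_m <- sqrt(2 * e^2 * NA_ * (1000 * ionic_strength) /
                    (eps0 * eps_r * kB * T_K))
  kappa_m * 1e-10
}

#' Screened Coulomb (Debye-Hueckel) pair energy
#'
#' @param qi,qj bead charges (elementary charges).
#' @param r separation (Angstrom), > 0; vectorised.
#' @param kappa inverse screening length (Angstrom^-1).
#' @param eps_r relative permittivity.
#' @return energy in kcal/mol.
#' @export
electrostatic_energy <- function(qi, qj, r, kappa = MPIPI_GLOBALS$kappa,
                                 eps_r = MPIPI_GLOBALS$eps_r) {
  if (any(r <= 0)) stop("separation must be positive", call. = FALSE)
  COULOMB_KCAL * qi * qj / (eps_r * r) * exp(-kappa * r)
}

#' Wang-Frenkel pair potential
#'
#' Finite-range Lennard-Jones-like potential
#' `phi(r) = eps * alpha * ((sigma/r)^(2 mu) - 1) * ((rc/r)^(2 mu) - 1)^(2 nu)`
#' for `r < rc` and exactly 0 beyond, with the normalisation `alpha` chosen
#' so the minimum depth equals `-eps`. It vanishes at `r = sigma` and
#' smoothly at the cutoff.
#'
#' @param r separation (Angstrom), > 0; vectorised.
#' @param eps well depth (kcal/mol).
#' @param sigma pair diameter (Angstrom).
#' @param mu,nu shape exponents (dimensionless).
#' @param rc cutoff (Angstrom), > sigma; default `3 * sigma`.
#' @return energy in kcal/mol.
#' @export
wang_frenkel_energy <- function(r, eps, sigma, mu = 1, nu = 1,
                                rc = 3 * sigma) {
  stopifnot(all(r > 0), rc > sigma)
  alpha <- wf_alpha(sigma, mu, nu, rc)
  out <- eps * alpha * ((sigma / r)^(2 * mu) - 1) *
    ((rc / r)^(2 * mu) - 1)^(2 * nu)
  out[r >= rc] <- 0
  out
}

wf_alpha <- function(sigma, mu, nu, rc) {
  x <- (rc / sigma)^(2 * mu)
  2 * nu * x * ((1 + 2 * nu) / (2 * nu * (x - 1)))^(2 * nu + 1)
}

# ---- Parameter tables -------------------------------------------------------

#' Load a model parameter table from a YAML file
#'
#' Schema: a `residues` block mapping one-letter codes to
#' `{mass, charge, sigma}`; a `pairs` list of
#' `{i, j, eps, sigma, mu, nu[, rc]}` entries; and a `globals` block
#' (`k`, `r0`, `eps_r`, `kappa`), missing globals filled from the model
#' defaults. Pairs are symmetric: a missing `(j, i)` entry is completed from
#' `(i, j)`; conflicting duplicates are rejected.
#'
#' @param path path to the YAML parameter file.
#' @return object of class `mpipi_params`: list with `residues`
#'   (data.frame), `pairs` (named list keyed `"i:j"` with both orders
#'   present), and `globals`.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (blk in c("residues", "pairs")) {
    if (is.null(raw[[blk]])) {
      stop("parameter file missing block: ", blk, call. = FALSE)
    }
  }
  res <- do.call(rbind, lapply(names(raw$residues), function(a) {
    e <- raw$residues[[a]]
    need <- setdiff(c("mass", "charge", "sigma"), names(e))
    if (length(need) > 0) {
      stop("residue ", a, " missing keys: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    data.frame(residue = a, mass = e$mass, charge = e$charge,
               sigma = e$sigma, stringsAsFactors = FALSE)
  }))
  pairs <- list()
  for (e in raw$pairs) {
    need <- setdiff(c("i", "j", "eps", "sigma", "mu", "nu"), names(e))
    if (length(need) > 0) {
      stop("pair entry missing keys: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(e$rc)) e$rc <- 3 * e$sigma
    val <- e[c("eps", "sigma", "mu", "nu", "rc")]
    for (key in c(paste(e$i, e$j, sep = ":"), paste(e$j, e$i, sep = ":"))) {
      if (!is.null(pairs[[key]]) && !isTRUE(all.equal(pairs[[key]], val))) {
        stop("conflicting asymmetric parameters for pair ", key,
             call. = FALSE)
      }
      pairs[[key]] <- val
    }
  }
  globals <- utils::modifyList(MPIPI_GLOBALS,
                               if (is.null(raw$globals)) list()
                               else raw$globals)
  structure(list(residues = res, pairs = pairs, globals = globals),
            class = "mpipi_params")
}

pair_params <- function(params, a, b) {
  p <- params$pairs[[paste(a, b, sep = ":")]]
  if (is.null(p)) {
    stop("no pair parameters for (", a, ", ", b, ")", call. = FALSE)
  }
  p
}

#' Construct a bead configuration
#'
#' @param residues character vector of one-letter codes, one per bead.
#' @param xyz numeric matrix (n x 3) of positions in Angstrom.
#' @param bonds integer matrix (m x 2) of bonded bead index pairs; default
#'   a linear chain.
#' @return object of class `bead_config`.
#' @export
bead_config <- function(residues, xyz,
                        bonds = cbind(seq_len(length(residues) - 1L),
                                      seq_len(length(residues) - 1L) + 1L)) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == length(residues), ncol(xyz) == 3,
            all(is.finite(xyz)))
  if (length(residues) < 2L) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 &&
      (max(bonds) > length(residues) || min(bonds) < 1L)) {
    stop("bond indices out of range", call. = FALSE)
  }
  structure(list(residues = toupper(residues), xyz = xyz, bonds = bonds),
            class = "bead_config")
}

#' Read a bead configuration from a coordinate table
#'
#' Expects a CSV with columns `bead`, `residue`, `x`, `y`, `z` (Angstrom)
#' and optional columns `bond_i`, `bond_j` giving the topology; without
#' them a linear chain is assumed.
#'
#' @param path CSV path.
#' @return a [bead_config()].
#' @export
read_config <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[order(tab$bead), ]
  bonds <- if (all(c("bond_i", "bond_j") %in% names(tab))) {
    b <- tab[!is.na(tab$bond_i), c("bond_i", "bond_j")]
    as.matrix(b)
  } else {
    cbind(seq_len(nrow(tab) - 1L), seq_len(nrow(tab) - 1L) + 1L)
  }
  bead_config(tab$residue, as.matrix(tab[, c("x", "y", "z")]), bonds)
}

#' Total model energy of a bead configuration, decomposed by term
#'
#' Sums harmonic bond energies over the topology and, over all non-bonded
#' bead pairs (standard 1-2 exclusion), the screened electrostatic and
#' Wang-Frenkel terms, the latter cut off at each pair's `rc`.
#'
#' @param config a [bead_config()].
#' @param params an `mpipi_params` table from [load_params()].
#' @return list with `bond`, `elec`, `pair` and `total` (kcal/mol).
#' @export
total_energy <- function(config, params) {
  stopifnot(inherits(config, "bead_config"),
            inherits(params, "mpipi_params"))
  unknown <- setdiff(unique(config$residues), params$residues$residue)
  if (length(unknown) > 0) {
    stop("residues missing from parameter table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  g <- params$globals
  q <- stats::setNames(params$residues$charge, params$residues$residue)
  n <- length(config$residues)
  e_bond <- 0
  bonded <- matrix(FALSE, n, n)
  if (nrow(config$bonds) > 0) {
    for (b in seq_len(nrow(config$bonds))) {
      i <- config$bonds[b, 1]; j <- config$bonds[b, 2]
      r <- sqrt(sum((config$xyz[i, ] - config$xyz[j, ])^2))
      e_bond <- e_bond + bond_energy(r, g$k, g$r0)
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  }
  e_elec <- 0
  e_pair <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (bonded[i, j]) next
        r <- sqrt(sum((config$xyz[i, ] - config$xyz[j, ])^2))
        qi <- unname(q[config$residues[i]])
        qj <- unname(q[config$residues[j]])
        if (qi != 0 && qj != 0) {
          e_elec <- e_elec +
            electrostatic_energy(qi, qj, r, g$kappa, g$eps_r)
        }
        pp <- pair_params(params, config$residues[i], config$residues[j])
        e_pair <- e_pair + wang_frenkel_energy(r, pp$eps, pp$sigma,
                                               pp$mu, pp$nu, pp$rc)
      }
    }
  }
  list(bond = e_bond, elec = e_elec, pair = e_pair,
       total = e_bond + e_elec + e_pair)
}
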