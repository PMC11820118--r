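test_that("harmonic bond term is a parabola anchored at r0", {
  expect_equal(bond_energy(3.81), 0)
  expect_equal(bond_energy(4.81), 9.55)
  d <- runif(5, 0, 2)
  expect_equal(bond_energy(3.81 + d), bond_energy(3.81 - d))
})

test_that("Debye screening length reproduces physiological salt", {
  expect_equal(debye_kappa(0), 0)
  expect_equal(round(debye_kappa(0.150, eps_r = 80, T_K = 300), 3), 0.126)
  # square-root scaling in ionic strength
  expect_equal(debye_kappa(0.4), 2 * debye_kappa(0.1), tolerance = 1e-12)
})

test_that("screened Coulomb term has the right magnitude and monotonicity", {
  expect_equal(electrostatic_energy(0, 1, 5), 0)
  # at r = 1/kappa the screened interaction is 332.06/(eps_r r) / e
  r <- 1 / 0.126
  expect_equal(electrostatic_energy(1, 1, r),
               332.0637 / (80 * r) * exp(-1), tolerance = 1e-6)
  expect_equal(round(electrostatic_energy(1, 1, r), 3), 0.192)
  rr <- seq(2, 20, by = 0.5)
  expect_true(all(diff(electrostatic_energy(1, 1, rr)) < 0))
  expect_error(electrostatic_energy(1, 1, 0), "positive")
})

test_that("Wang-Frenkel potential vanishes at sigma and rc with depth -eps", {
  eps <- 0.8; sigma <- 5
  expect_equal(wang_frenkel_energy(sigma, eps, sigma), 0)
  expect_equal(wang_frenkel_energy(3 * sigma, eps, sigma), 0)
  expect_equal(wang_frenkel_energy(10 * sigma, eps, sigma), 0)
  # numerical minimum over (sigma, rc): grid scan then golden-section refine
  opt <- optimize(function(r) wang_frenkel_energy(r, eps, sigma),
                  interval = c(sigma, 3 * sigma), tol = 1e-10)
  expect_equal(opt$objective, -eps, tolerance = 1e-6)
  # no discontinuity at the cutoff
  expect_lt(abs(wang_frenkel_energy(3 * sigma - 1e-9, eps, sigma)), 1e-6)
})

test_that("parameter tables load with symmetric completion and validation", {
  p <- load_params(mini_params_path())
  expect_s3_class(p, "mpipi_params")
  expect_equal(nrow(p$residues), 3)
  expect_length(p$pairs, 9)  # 3 diagonal + both orders of 3 off-diagonal
  expect_equal(p$pairs[["G:R"]], p$pairs[["R:G"]])
  expect_equal(p$globals$k, 19.1)
  expect_equal(p$globals$kappa, 0.126)

  asym <- tempfile(fileext = ".yaml")
  writeLines(c("residues:",
               "  G: {mass: 57.0, charge: 0.0, sigma: 4.5}",
               "  R: {mass: 156.2, charge: 1.0, sigma: 6.6}",
               "pairs:",
               "  - {i: G, j: R, eps: 0.1, sigma: 5.5, mu: 1, nu: 1}",
               "  - {i: R, j: G, eps: 0.2, sigma: 5.5, mu: 1, nu: 1}"),
             asym)
  expect_error(load_params(asym), "conflicting")

  incomplete <- tempfile(fileext = ".yaml")
  writeLines(c("residues:", "  G: {mass: 57.0, charge: 0.0}"), incomplete)
  expect_error(load_params(incomplete), "missing")
})

test_that("total energy decomposes and matches the unit terms", {
  p <- load_params(mini_params_path())
  # two neutral beads at r = sigma_ij, unbonded: every term zero
  cfg0 <- bead_config(c("G", "G"),
                      rbind(c(0, 0, 0), c(4.5, 0, 0)),
                      bonds = matrix(integer(0), ncol = 2))
  e0 <- total_energy(cfg0, p)
  expect_equal(e0$total, 0)

  # bonded pair at r0: bond zero, and the 1-2 exclusion removes the rest
  cfgb <- bead_config(c("G", "G"), rbind(c(0, 0, 0), c(3.81, 0, 0)))
  eb <- total_energy(cfgb, p)
  expect_equal(eb$bond, 0)
  expect_equal(eb$elec, 0)
  expect_equal(eb$pair, 0)

  # three-bead chain: totals equal the sum of pairwise unit-op calls
  xyz <- rbind(c(0, 0, 0), c(4.2, 0, 0), c(8.0, 2.0, 0))
  cfg <- bead_config(c("R", "G", "D"), xyz)
  e <- total_energy(cfg, p)
  r12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  r23 <- sqrt(sum((xyz[2, ] - xyz[3, ])^2))
  r13 <- sqrt(sum((xyz[1, ] - xyz[3, ])^2))
  expect_equal(e$bond, bond_energy(r12) + bond_energy(r23),
               tolerance = 1e-12)
  expect_equal(e$elec, electrostatic_energy(1, -1, r13),
               tolerance = 1e-12)
  pp <- p$pairs[["R:D"]]
  expect_equal(e$pair,
               wang_frenkel_energy(r13, pp$eps, pp$sigma, pp$mu, pp$nu,
                                   pp$rc),
               tolerance = 1e-12)
  expect_equal(e$total, e$bond + e$elec + e$pair)

  expect_error(total_energy(bead_config("W", rbind(c(0, 0, 0)),
                                        matrix(integer(0), ncol = 2)), p),
               "missing from parameter table")
})

test_that("total energy is invariant under rigid motions and bead order", {
  p <- load_params(mini_params_path())
  set.seed(11)
  xyz <- matrix(rnorm(12, sd = 4), ncol = 3)
  cfg <- bead_config(c("R", "G", "D", "G"), xyz)
  e <- total_energy(cfg, p)
  for (i in 1:5) {
    # random rotation (QR of a Gaussian matrix) plus translation
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- sweep(xyz %*% R, 2, rnorm(3, sd = 10), "+")
    e2 <- total_energy(bead_config(c("R", "G", "D", "G"), moved), p)
    expect_equal(e2$total, e$total, tolerance = 1e-9)
    expect_equal(e2$bond, e$bond, tolerance = 1e-9)
  }
  # reversing the chain relabels beads and bonds but not the energy
  rev_cfg <- bead_config(rev(c("R", "G", "D", "G")), xyz[4:1, ])
  erev <- total_energy(rev_cfg, p)
  expect_equal(erev$total, e$total, tolerance = 1e-12)
})
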