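---
title: "Methods: binodal fitting, scaling laws and aromatic patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binodal fitting, scaling laws and aromatic patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldscale)
```

# Scope

`pldscale` analyses liquid–liquid phase separation of prion-like
low-complexity domains (PLDs). This vignette documents the methods and
the modelling choices behind each module: how coexisting densities and
critical points are fitted, how mutation-class scaling laws are defined,
fitted and applied, how the aromatic patterning order parameter is
normalised, and what the synthetic generators guarantee. Units
throughout: Kelvin, g/cm³, Ångström, kcal/mol, elementary charges.

# Coexisting densities from slab profiles

Direct-coexistence ("slab") simulations produce a protein mass density
profile ρ(z) along the long box axis with a dense slab between two
interfaces. `extract_coexisting_densities()` fits the double-tanh shape

ρ(z) = ρ_low + (ρ_high − ρ_low)/2 · [tanh((z − z1)/w) − tanh((z − z2)/w)]

by weighted nonlinear least squares (Levenberg–Marquardt, via
`minpack.lm`). Two robustness measures precede the fit:

* **Periodic recentring.** The slab may straddle the periodic box edge.
  The profile is rotated so that the circular mean of the density-weighted
  positions sits at the box centre, which makes the two-interface form
  valid regardless of where the slab happened to sit.
* **Degeneracy check.** If the profile is flat to machine precision the
  routine reports the mean density with `coexistence = FALSE` instead of
  attempting a singular fit.

After the fit, coexistence is also rejected when the plateau gap
ρ_high − ρ_low is smaller than three times its joint standard error —
near-critical profiles whose plateaus are statistically
indistinguishable should not enter a binodal.

# Critical-point fits

Coexisting densities over a temperature grid are condensed into a
critical point by two classical near-critical laws, fitted
simultaneously to both branches:

* coexistence law: (ρ_high − ρ_low)^3.06 = d · (1 − T/Tc),
* rectilinear diameters: (ρ_high + ρ_low)/2 = ρ_c + A · (T − Tc).

Equivalently, each branch is ρ±(T) = ρ_c + A(T − Tc) ±
½ [d(1 − T/Tc)]^(1/3.06). `fit_critical_point()` stacks both branches
into one weighted Levenberg–Marquardt problem with linear pre-fits
supplying the starting values and the box constraint Tc ≥ max(T). The
exponent 3.06 (i.e. an effective β ≈ 0.327, the 3D Ising value) is held
fixed: with ten temperatures per system a free exponent is poorly
constrained and would trade bias for variance. Critical-temperature
changes between a variant and its wild type are simple differences,
ΔTc = Tc(variant) − Tc(wt), with errors added in quadrature.

# Scaling laws for ΔTc

For a family of variants that mutate N residues of one class in a chain
of length L, three ansätze are considered:

| ansatz   | form              | interpretation                     |
|----------|-------------------|------------------------------------|
| count    | ΔTc = S·N         | each substitution acts independently of chain size |
| fraction | ΔTc = S·N/L       | the mutated fraction is what matters |
| sqrt     | ΔTc = S·N/√L      | intermediate, surface-like buffering |

Fits are **through the origin** (`fit_scaling_constant()`): zero
mutations change nothing by construction, so no intercept is estimated
and the coefficient of determination is defined against the raw sum of
squares, R² = 1 − SS_res/Σy². This convention makes R² values across
ansätze directly comparable but not comparable with intercept-model R².
`select_ansatz()` fits all three and picks the largest R²; when all
observations share one length the three covariates are proportional and
the result is flagged `indistinguishable` instead of reporting a
spurious winner.

Two structural properties are enforced rather than estimated:
antisymmetry, S(X1→X2) = −S(X2→X1) (`reverse_law()`), and additivity of
independent single-class mutations with errors combined in quadrature
(`cumulative_prediction()`).

The package ships a set of previously fitted constants
(`published_laws()`) covering nine mutation classes — for example
Y→F (count, −0.40 K), F/Y→W (count, +4.3 K), R→K (fraction, −1300 K per
unit fraction), R→X (fraction, −640 K per unit fraction), F/Y→X (sqrt,
−56 K·√residues). These are data, not refit at load time; the G→S class
is known only qualitatively and deliberately ships without a constant,
so predictions for it refuse rather than guess. `build_table1()`
evaluates the constants for one substitution at L = 100/200/300,
reporting raw values alongside a rounded view (2 significant figures for
the value, 1 for the error, with halves rounded away from zero).

```{r}
build_table1()[1:6, ]
```

# Worked example

```{r}
laws <- published_laws()
# one R->K substitution in a 200-residue PLD
predict_delta_tc(mutation_spec("R", "K", 1), 200, laws[["R->K"]])
# cumulative: 2 Y->F plus 1 N->Q in the same chain
cumulative_prediction(list(mutation_spec("Y", "F", 2),
                           mutation_spec("N", "Q", 1)), 200)
```

# Mutation grammar and variant design

Variants are named with a `-nX+mZ` grammar (e.g. `-4R+4K`, `-6Y`,
`-4F/Y+4W`); `parse_variant_label()` accepts both ASCII hyphens and the
typographic minus and rejects unbalanced substitutions. `design_variant()`
places the N mutated residues at evenly spaced quantiles of the source
positions (index 1 + round((j−1)(M−1)/(N−1)) among M occurrences), so
designed variants perturb patterning as little as possible. Deletions to
"X" (uncharged, non-aromatic) draw replacements from the weak-spacer
pool S/T/G/A in proportion to the sequence's own composition via
largest-remainder apportionment, conserving length and the untouched
classes exactly; `infer_mutation()` recovers the spec from the pair of
sequences.

# Aromatic patterning: σ_aro

Stickers-and-spacers phenomenology says that, at fixed composition,
clustering the aromatic stickers strengthens condensates. The order
parameter quantifies aromatic clustering by blocking the sequence into
windows of length l (the final partial window keeps its true length):

* global asymmetry σ_T = (2·N_aro/L − 1)²,
* per-window asymmetry σ_i = ((2·n_aro,i/l_i − 1)² − σ_T)²,
* σ_aro = [Σ_i σ_i / σ_i^max] · N_stickers/L,

where σ_i^max is the per-window asymmetry profile of a maximally
clustered reference — all aromatics packed at the head of the chain,
spacers behind — and the sticker count includes aromatics and charged
residues (histidine counts as a sticker by default; the charge model is
configurable). Windows where σ_i^max = 0 contribute 0 (the 0/0 guard).
The default windows are l = 5 and 6, bracketing typical sticker spacing
in natural PLDs. Scores are reported for both; they are close in
practice and neither is privileged.

**Anchoring choice.** The maximally clustered reference is anchored at
the head of the chain. Any single-block arrangement gives the same
multiset of window asymmetries up to the interface window, so anchoring
is a tie-breaking convention; it is applied identically to every
sequence, which is what comparisons require.

**Normalisation caveat.** The per-window ratio σ_i/σ_i^max makes scores
comparable across compositions, but it is a sum of ratios, and the
reference's *interface* window (the one containing the head/tail
boundary) can have a tiny σ_i^max. A sequence that places even one
aromatic in that particular window picks up a huge ratio there. As a
consequence "clustered ≥ dispersed" is guaranteed only against
*perfectly even* dispersal — when every window matches the global
aromatic fraction, all σ_i vanish and σ_aro = 0, its global minimum —
while merely "as even as possible" arrangements can occasionally
outscore a clustered one through the interface-window term. σ_aro is
therefore best read as a distance from perfect evenness under a
composition-dependent normalisation, not as a total order on
arrangements.

```{r}
clustered <- pld_sequence("c", c(rep("Y", 8), rep("G", 32)))
dispersed <- pld_sequence("d", rep(c("Y", "G", "G", "G", "G"), 8))
c(clustered = sigma_aro(clustered, 5)$sigma_aro,
  dispersed = sigma_aro(dispersed, 5)$sigma_aro)
```

# Residue-level energy model

The energy module evaluates the terms of a one-bead-per-residue
coarse-grained model: harmonic bonds ½k(r − r0)² with k = 19.1
kcal mol⁻¹ Å⁻² and r0 = 3.81 Å; Debye–Hückel screened electrostatics
q_i q_j e^(−κr)/(4πε₀ε_r r) with ε_r = 80 and κ = 0.126 Å⁻¹ (150 mM
monovalent salt at 300 K — `debye_kappa()` recomputes κ from first
principles with CODATA constants); and Wang–Frenkel pair interactions

φ(r) = ε α [(σ/r)^2μ − 1] [(r_c/r)^2μ − 1]^2ν for r < r_c, else 0.

The prefactor α is not a free parameter: requiring the minimum depth to
equal −ε fixes α = 2ν (r_c/σ)^2μ [(1 + 2ν) / (2ν ((r_c/σ)^2μ − 1))]^(2ν+1),
which the package derives internally (`wf_alpha()`) rather than tabulating.
The potential vanishes at r = σ, at the cutoff (default r_c = 3σ) and
beyond, and is exactly finite-ranged. `total_energy()` sums bonds over
the topology and, over non-bonded pairs (standard 1–2 exclusion), the
electrostatic and Wang–Frenkel terms; parameter tables load from YAML
with symmetric completion of missing (j, i) entries and rejection of
conflicting duplicates. The shipped `mpipi_params_mini.yaml` is an
illustrative three-residue fixture for tests and examples, not a
production force field.

# Synthetic data with known truth

The datasets on which models of this kind are fitted come from
cluster-scale molecular dynamics (hundreds of slab simulations,
millions of CPU hours) and cannot be regenerated at desk scale. The
package therefore validates its entire analysis chain on synthetic data
that emulates the *statistical shape* of those observables with known
ground truth:

* `synth_density_profile()` — double-tanh slab plus i.i.d. Gaussian
  noise;
* `synth_coexistence_points()` — points on the closed-form binodal of a
  chosen critical point, plus noise;
* `synth_variant_family()` — ΔTc observations from a chosen ansatz and
  constant, plus noise;
* `synth_pld_sequence()` — random sequences hitting PLD-like class
  compositions by largest-remainder rounding.

Each generator is a deterministic function of (truth, seed) and attaches
its truth as an attribute (serialisable with `write_truth()`), so any
fit can be scored against what generated the data. Default problem
sizes (10 temperatures, 200 profile bins, 20 observations per family,
noise of 0.01 g/cm³ on densities and 2 K on ΔTc) are package choices
made to resemble realistic per-system statistics while keeping every
check under a minute. One calibration worth knowing: at that density
noise the critical-point fit's own Tc standard error is ≈ 1.5 K, so a
"recovered within 2 K" check is a fixed-seed statement (≈ 1.35 standard
errors), not a bound that every random seed satisfies.

# Reproducing the full analysis

The repository's `analysis/` directory contains numbered drivers that
regenerate everything from scratch into `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic dataset + truths
Rscript analysis/02_fit_binodals.R  # plateaus, critical points, delta Tc
Rscript analysis/03_scaling_laws.R  # ansatz fits + prediction grid
Rscript analysis/04_patterning.R    # composition and sigma_aro tables
Rscript analysis/05_report.R        # end-to-end pipeline report (JSON)
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the headline numbers against the installed package.
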