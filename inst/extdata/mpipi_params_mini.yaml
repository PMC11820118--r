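# Minimal synthetic parameter table for the coarse-grained model, covering
# three residues (G, R, D). Values are illustrative fixtures for testing
# the energy-evaluation code paths, not a published force-field release;
# a production run consumes the full per-pair table distributed with the
# force field.
residues:
  G: {mass: 57.05, charge: 0.0, sigma: 4.5}
  R: {mass: 156.19, charge: 1.0, sigma: 6.56}
  D: {mass: 115.09, charge: -1.0, sigma: 5.58}
pairs:
  - {i: G, j: G, eps: 0.10, sigma: 4.50, mu: 1, nu: 1}
  - {i: G, j: R, eps: 0.15, sigma: 5.53, mu: 1, nu: 1}
  - {i: G, j: D, eps: 0.12, sigma: 5.04, mu: 1, nu: 1}
  - {i: R, j: R, eps: 0.20, sigma: 6.56, mu: 1, nu: 1}
  - {i: R, j: D, eps: 0.25, sigma: 6.07, mu: 1, nu: 1}
  - {i: D, j: D, eps: 0.18, sigma: 5.58, mu: 1, nu: 1}
globals:
  k: 19.1
  r0: 3.81
  eps_r: 80
  kappa: 0.126
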