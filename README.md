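# coacerv

Coarse-grained modelling of charge-driven phase separation between RNA and
globular proteins.

Compact RNA molecules and common folded proteins can demix into dense
condensates purely through electrostatic complementarity — no disordered
polymers or specific binding sites required. `coacerv` implements a
colloid-type spherical model of this process end to end: every
macromolecule is a sphere with a radius and an effective net charge, pairs
interact through a short-range 10–5 Lennard-Jones potential plus a
size-scaled Debye–Hückel term,

$$U(r) = 4\varepsilon\left[(\sigma_{ij}/r)^{10} - (\sigma_{ij}/r)^{5}\right]
 + (A_{ij} + A_0)\,\frac{\kappa\sigma_{ij}}{r}\, e^{-r/\kappa\sigma_{ij}},$$

and the package provides:

* a seeded Langevin dynamics engine (BAOAB, periodic cubic box, compiled
  kernel) with builders for binary RNA–protein mixtures, a reduced
  five-component cytoplasm and a synthetic polydisperse cytoplasm;
* condensate detection by contact graphs (centre distance
  $< \sigma_{ij} + \delta$, $\delta$ = 0.7/2.2 nm), cluster size
  distributions, Monte-Carlo condensate volumes, radial distribution
  functions, phase volume fractions and critical-point fits
  ($\phi_H-\phi_L = A(T_c-T)^{0.32}$);
* mean-squared-displacement analysis and phase-resolved diffusion
  coefficients ($D_{tr} = \mathrm{MSD}/6\tau$);
* an analytical two-component coacervation theory: chemical potentials
  from $g(r)$-convolved enthalpies and density-ratio entropies, coexistence
  by constrained free-energy minimization over five candidate scenarios,
  with concentration, charge–radius and temperature phase maps;
* forward models for FRET efficiencies (label partitioning between phases,
  Förster-kernel convolution) and DLS correlation functions (cluster-ladder
  multi-exponential model with a seeded Levenberg–Marquardt fitter).

The methods vignette (`vignettes/coacervation-model.Rmd`) documents the
model, every tunable parameter and the design choices.

## Worked example

A desk-scale direct-coexistence run of the RNA–trypsin mixture at the
standard conditions (0.493 mM RNA, 0.350 mM trypsin, screening factor
0.7), followed by condensate analysis:

```r
library(coacerv)

p    <- interaction_params(kappa = 0.7, cutoff_nm = 12,
                           switch_on_nm = 11.5, charge_model = "eq5")
spec <- build_binary("trypsin", 0.493, 0.350, box_nm = 55, params = p)
co   <- droplet_placement(spec, seed = 9, radius_nm = 15)
tr   <- run_simulation(spec, co, simulation_params(n_steps = 1e6,
                       save_interval_steps = 2e4, seed = 4))

crit <- contact_criterion(2.2, pair_classes = list(list(A = "RNA", B = "trypsin")))
phase_fractions(tr, "RNA", crit, frames = 31:51)
#> <phase_fractions> species RNA: PS = TRUE (fraction in clusters >= 10: 0.66)
#>   mean phi_H = 0.08583, mean phi_L = 0.001386 over 21 frames
```

Most RNA stays in one large cluster (phase separation), with a dense
condensate ($\phi_H \approx 0.09$ RNA volume fraction) coexisting with a
thin vapour. The analytical theory makes the matching prediction from
first principles in seconds:

```r
sol <- solve_coexistence(theory_input(q_P = 6, r_P_nm = 1.81,
                                      c_R_mM = 0.45, c_P_mM = 0.35))
sol
#> <theory_solution> scenario 3 (both-coexist) [phase separated], dG = 0.0005314 kJ/mol/V
#>   dilute:    [R] = 0.3312 mM, [P] = 0.1754 mM
#>   condensed: [R] = 10.16 mM, [P] = 14.61 mM (Vc/V = 0.0121)
```

— a millimolar-scale RNA/protein condensate occupying ~1% of the volume,
pinned at the 30% packing cap. Swapping in `q_P = -17, r_P_nm = 2.58`
(a serum-albumin-like negative protein) returns scenario 1: no phase
separation.

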