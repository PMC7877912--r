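---
title: "A coarse-grained model of charge-driven RNA-protein phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of charge-driven RNA-protein phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacerv)
```

## The model

`coacerv` studies complex coacervation — liquid–liquid phase separation
driven by electrostatic complementarity — between compact, roughly globular
RNA molecules and folded proteins, using a colloid-type coarse-grained
representation. Every macromolecule is a single sphere characterised by a
radius $r_i$ (the radius of the sphere with the molecule's volume) and a
nominal net charge $q_i$. Two particles at centre distance $r$ interact
through

$$U(r) = 4\varepsilon\left[\left(\frac{\sigma_{ij}}{r}\right)^{10}
 - \left(\frac{\sigma_{ij}}{r}\right)^{5}\right]
 + (A_{ij} + A_0)\,\frac{\kappa\sigma_{ij}}{r}\,
   e^{-r/\kappa\sigma_{ij}},$$

a short-range 10–5 Lennard-Jones term plus a Debye–Hückel term whose
screening length $\kappa\sigma_{ij}$ scales with particle size (screened
charges sit mostly near the surface, and this keeps the screening
physically comparable between small proteins and large complexes). The
parameters:

* $\varepsilon = 4$ kJ/mol, one well depth for all particles;
* $\sigma_i = 2^{-1/6} r_i$, additive: $\sigma_{ij} = \sigma_i + \sigma_j$;
* $A_0 = 3$ kJ/mol, a universal repulsive baseline (solvation repulsion
  between polar but neutral macromolecules);
* $A_{ij} = A_i A_j$ with $A_i = \mathrm{sign}(q_i)\sqrt{0.75\,|q_{\mathrm{eff},i}|}$,
  so unlike charges attract ($A_{ij}<0$) and like charges repel;
* $\kappa$, dimensionless; for a reference pair size $\sigma_{ii} = 3$ nm at
  298 K, $\kappa = 0.5, 1.0, 1.5$ correspond to roughly 40, 10 and 5 mM of
  monovalent salt (`kappa_to_salt_mM()`), counted *after* counterion
  condensation.

Effective charges absorb counterion condensation around highly charged
molecules. Two empirical forms are provided (`effective_charge()`): a
logarithmic one, $q_\mathrm{eff} = \mathrm{sign}(q)\,20\ln(|q|/20+1)$, and a
square-root one, $q_\mathrm{eff} = \mathrm{sign}(q)\,0.6\sqrt{|q|\ln(|q|/2+1)}$.
Both leave small charges nearly nominal and strongly reduce large ones
(a 4000-charge ribosome-like particle maps to roughly $-100$). The
logarithm base is exposed as an option: published consistency estimates for
DNA-scale charges favour a decadic reading while ribosome-scale estimates
favour the natural one, and no single base satisfies both. The simulator
defaults to the logarithmic form with natural log; the analytical theory
defaults to the square-root form (below).

## Simulation engine

`run_simulation()` integrates Langevin dynamics with a BAOAB splitting:
the two deterministic half-kicks and drifts sandwich an exact
Ornstein–Uhlenbeck update of the velocities, which gives accurate
configurational sampling at the 1 ps production timestep. Thermostat
defaults are 298 K and friction 1/ps. The box is cubic and periodic with
minimum-image distances; the pair potential is evaluated up to a cutoff
(production: 49.5 nm, switched off smoothly from 49 nm by a quintic
$C^2$ smoothstep; a $C^2$ switch avoids the slow thermostat-masked heating
that a truncated force would cause). Desk-scale systems may reduce the
cutoff proportionally with the box (`allow_reduced_cutoff`); at
$\kappa \le 1$ the screened interaction is negligible beyond ~12 nm, so
this changes nothing measurable in the reduced systems.

Masses are not part of the published protocol. Equilibrium observables —
cluster statistics, $g(r)$, phase fractions — are mass-independent, but
diffusion coefficients are not. The default assigns each sphere the mass of
its volume at 1.35 g/cm³ (a typical macromolecular density); a unit-mass
mode exists for property tests. Absolute $D_{tr}$ values are therefore a
convention, and only ratios and inequalities between phases should be
compared across implementations; the trajectory provenance records the
mass model for this reason.

The interaction kernel and integrator are compiled (Rcpp); the thermostat
noise stream is seeded and reproducible on a fixed platform.

## Condensate detection and phase analysis

Two particles are "in contact" when their centre distance is strictly below
$\sigma_{ij} + \delta$. $\delta = 0.7$ nm captures direct molecular
interactions (transient clusters); $\delta = 2.2$ nm includes everything
inside the first peak of the pair correlation function and is the
condensate criterion. Contacts restricted to chosen species pairs (e.g.
RNA–protein only) build a contact graph whose connected components are the
clusters (`contact_graph()`, `connected_clusters()`; igraph supplies the
component search, and the test suite checks it against a brute-force
transitive closure).

A condensate is a cluster of at least 10 members. The published criterion —
"at least half of the particles in one or a few large clusters" — does not
state a size threshold; 10 was fixed here once, and the analysis functions
expose it (`min_cluster_size`) so sensitivity to 5/10/20 can be checked
directly. Condensate volume is the volume of the union of member spheres
inflated by a 2.2 nm probe, estimated by seeded Monte-Carlo sampling to a
target relative standard error of 1% (`condensate_volume()`; a
deterministic voxel-grid version cross-checks it to 2%). The dilute-phase
volume is the box volume minus *all* condensate volumes (when several
condensates coexist, subtracting only the largest is the other published
reading; subtracting all is the default here and the choice is flagged in
the function documentation). Volume fractions $\phi_H$ (inside) and
$\phi_L$ (outside) follow, and coexistence curves over temperature are
fitted by `fit_critical_point()` to

$$\phi_H-\phi_L = A\,(T_c-T)^{0.32}, \qquad
  \tfrac12(\phi_H+\phi_L) = \phi_c + B\,(T-T_c),$$

with the 3D-Ising exponent 0.32 held fixed; for a trial $T_c$ both
relations are linear least-squares problems, and $T_c$ is profiled.

## Desk-scale condensation protocol

Nucleation of condensates from uniformly random starts takes tens of
microseconds to milliseconds of model time — far beyond a desk-scale
budget. The package therefore uses a direct-coexistence style protocol for
small systems: all particles start in a compact non-overlapping droplet
(`droplet_placement()`), and the question asked of the microsecond-scale
run is whether the droplet *persists* (a phase-separating system keeps a
majority cluster and sheds a dilute vapour) or *evaporates* (a
non-separating system disperses). At the standard binary conditions
(0.493 mM RNA, 0.350 mM protein, $\kappa = 0.7$, logarithmic charges,
55 nm box, 84 particles, $10^6$ steps = 1 µs), RNA–trypsin and
RNA–lysozyme droplets persist with 70–80% of RNA in the largest cluster,
while an RNA–myoglobin droplet shrinks below the 50% mark — the same
qualitative ordering as the full-scale published simulations, at a
$10^6$-fold smaller compute budget. Quantities from these runs
(condensed-phase concentrations, dilute fractions) are desk-scale proxies:
finite-size effects (interface fraction, particle-count granularity) keep
them from matching full-scale values quantitatively.

## Analytical coacervation theory

The theory (`theory_input()`, `solve_coexistence()`) treats a two-component
mixture of R (RNA-like, charge $q_R$, radius $r_R$) and P (protein-like)
particles at total number densities $\rho_R, \rho_P$ in a unit volume. A
condensed phase of volume $V_c$ may coexist with a dilute phase; mass
conservation fixes the condensed densities given $V_c$ and the dilute
densities. Chemical potentials are $\mu = \Delta h - T\Delta s$ with

* enthalpies from the pair potential convolved with tabulated, radially
  rescaled radial distribution functions:
  $x_{\mathrm{pair,phase}} = 2\pi\int_0^{r_\mathrm{max}} \hat g(r)\,U(r)\,r^2\,dr$
  ($r_\mathrm{max}$ = 100 nm; $\hat g$ truncated to 1 beyond 20 nm; the
  common $2\pi = \tfrac12 \cdot 4\pi$ factor halves every pair so each
  interaction is counted once in the total free energy), and
  $\Delta h_{R} = \rho_R x_{RR} + \rho_P x_{RP}$ per phase;
* entropies from density ratios relative to the fully disperse state,
  $\Delta s = R\ln(\rho_\mathrm{total}/\rho_\mathrm{phase})$, with the
  condensed phase carrying an excluded-volume factor
  $1 - (\rho_{R,c}V_R + \rho_{P,c}V_P)$.

Theory defaults differ from the simulator where the published calibration
differs: square-root effective charges and $\kappa = 1.17$. Five candidate
states are compared by total free energy: fully disperse (evaluated with
disperse-reference $\hat g$), fully condensed, both species coexisting,
and R-only / P-only coexistence. The total free energy includes the
between-species mixing entropy of each phase.

**Where solutions live.** The condensed-phase packing fraction is capped
(default 30%; the model's enthalpy keeps gaining from density because
excluded volume enters only through the entropy factor, so without a cap
the condensed phase would collapse). The coexistence equations
$\mu_d = \mu_c$ typically have roots only *above* the cap; the physical
solution is then the constrained free-energy minimum *on* the cap. The
solver handles both cases: interior optima are found by Newton–Raphson on
the chemical-potential equalities (scanning $V_c$ on a 400-point log grid
with a 200-point inner density scan, tolerance $10^{-12}$), and cap-bound
optima by one-dimensional minimization along the packing boundary with
Newton polishing of the tangential derivative. The returned object reports
which case applies (`at_packing_limit`), the equality residuals where they
are meaningful, and the stationarity (KKT) residual on the boundary. At the
standard binary conditions all phase-separating solutions sit at the cap.

**The $\hat g(r)$ library.** The reference tables shipped with the package
are generated by its own simulator from a binary RNA/trypsin-sized system
(see `inst/extdata/gofr/README` for every parameter and seed): a dense box
at condensed-phase concentrations for the condensed tables, a large dilute
box for the dilute tables, and pre-condensation frames at the total
concentrations for the disperse reference. For other particle sizes the
radial axis is rescaled by $r_R/r_{R,\mathrm{MD}}$, $r_P/r_{P,\mathrm{MD}}$
and their sum for the cross pair. Any user table in the same format can be
substituted.

**What the theory reproduces, and what it does not.** With the packaged
tables the theory discriminates by charge — trypsin, lysozyme, LDH, ADH
and cytochrome-C-like inputs phase separate at 0.45/0.35 mM with mM-scale
condensed RNA concentrations; strongly negative proteins (BSA-like) never
do; PS vanishes at high temperature and reappears nowhere; excess RNA
redissolves the condensates (reentrance); and a minimum protein
concentration is required. Three knife-edge features are *not* reproduced
quantitatively: the myoglobin point ($q=+2$) lands marginally inside the
PS region rather than marginally outside; the PS onset along the protein
axis sits near 0.3 mM rather than 0.1–0.15 mM; and PS flags are robust to
the packing cap over 0.3–0.4 but not down to 0.2. All three trace to the
enthalpy integrals being a few tens of percent weaker than the published
calibration, which is within the uncertainty contributed by the
unpublished reference distribution functions. The free-energy margin at
the myoglobin point is about 1% of the disperse free energy — smaller
than the statistical uncertainty of the tables — so its side of the
boundary should be considered undetermined by this reimplementation.
Relatedly, near $q \approx 0$ the universal Lennard-Jones well (2.5 kJ/mol
net of the $A_0$ repulsion, i.e. $\varepsilon_{\rm eff}/k_BT \approx 1$)
combined with condensate-like coordination makes large *neutral* spheres
marginally condense in the mean-field theory, although the simulator shows
such droplets evaporating — a known limitation of importing a fixed
condensed-phase structure into a near-critical fluid.

## Dynamics

`msd()` computes time- and particle-averaged mean-squared displacements on
the unwrapped trajectory (per-interval minimum-image accumulation; the
save interval must keep per-frame displacements under a quarter box, which
is validated). An optional membership filter keeps only windows during
which a particle remained inside (or outside) a condensate for the entire
lag. `fit_diffusion()` fits $\mathrm{MSD} = 6D\tau$ through the origin,
with the two published protocol windows (20 ns for finely-saved cytoplasm
segments, 2 µs for coarsely-saved long runs) as presets.

## Spectroscopic forward models

*FRET.* The theory's dilute/condensed RNA split is converted to
total-volume concentrations $[R_d], [R_c]$; dye-labeled RNA partitions
between the phases with an equilibrium constant $K$ (default 100 — the
hydrophobic dyes favour the less-hydrated condensate), giving the labeled
fraction in the condensate $f$ as the root of a quadratic
(`fret_fraction_condensed()`; conservation is exact). The measured
efficiency is $E = E_0(1-f) + E_c f$ with $E_0 = 0.24$ the zero-protein
baseline and $E_c$ obtained by convolving the condensed-phase minimum
RNA–RNA distance distribution with the Förster kernel
$1/(1+(r/r_0)^6)$, $r_0 = 4.10$ nm (`fret_Ec()`,
`min_distance_distribution()`).

*DLS.* `dls_g2_model()` builds the intensity correlation function
$g_2(\tau)-1$ of a polydisperse sample as a sum of squared field
correlations: a ten-rung ladder of cluster sizes $i^\nu d_c$ with
amplitudes decaying as $e^{-i/t_c}$ (modelling the exponential cluster-size
distribution of the dilute phase; $\nu = 1$ by default, $\nu = 1/3$ for
volumetric growth — the source description is ambiguous and both are
exposed), plus up to four discrete sizes. Each size decays as
$\exp(-2q^2D(d)\tau)$ with the scattering vector from the instrument
geometry (defaults: $n = 1.335$, 633 nm, 173°) and Stokes–Einstein
diffusion at 0.8882 cP. `dls_fit()` is a seeded multi-start
Levenberg–Marquardt fit; its reported $\chi^2$ is the mean squared
residual, a convention that is not comparable across instruments.

## Synthetic cytoplasm generator

`build_synthetic_cytoplasm()` emulates a crowded, polydisperse bacterial
cytoplasm when no measured composition table is available: log-normal
radii (median ≈ 2.2 nm), a charge mixture of many small positive/negative
proteins plus RNA-like species at $q \in [-100,-25]$ and one
ribosome-like class ($r = 10$ nm, $q = -4000$), filled to a target total
volume fraction (default 30%, the crowding level of a bacterial
cytoplasm) within ±1%. It is deterministic under its seed and emits a
manifest of realized parameters. It reproduces the *statistics* of a
cytoplasm (size and charge polydispersity, crowding), not any specific
organism's composition — results on it demonstrate that the machinery
scales to heterogeneous mixtures, nothing more.

## Problem sizes used by the test suite

Simulation tests run 84-particle binary systems for $10^6$ steps (1 µs),
two-particle Boltzmann checks for $2\times10^6$ steps, and the theory at
scan resolutions of 40–80 $V_c$ points (the solver's default is 400).
These sizes were chosen so the full suite exercises every code path at
statistically meaningful but desk-friendly scales; the vignette section on
desk-scale protocols explains why the qualitative conclusions are already
stable there.
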