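Reference radial distribution function library for the coacervation theory
===========================================================================

Nine tables (pairs RR, RP, PP x phases dilute, condensed, disperse), each a
two-column TSV (r_nm, g), plus library.json naming the source radii
(r_R_MD = 1.47 nm, r_P_MD = 1.81 nm) and the truncation radius (20 nm,
beyond which g is treated as exactly 1).

These tables are generated by the package's own Langevin simulator -- they
are a package-built stand-in for condensate structure factors, not
experimental data. Source system: binary J345-RNA / trypsin-sized spheres,
kappa = 0.7, logarithmic effective-charge model, 298 K. Reference states:

  condensed : 18 nm box at condensed-phase concentrations (16.5 / 15.2 mM),
              2e6 steps, first 100 frames discarded, seed 101
  dilute    : 80 nm box at 0.13 / 0.09 mM, 3e6 steps, seed 102
  disperse  : 55 nm box at the total concentrations (0.493 / 0.350 mM),
              short 2e5-step runs from uniform random starts (before
              condensates form), averaged over seeds 103-108

Regenerate with:  Rscript inst/scripts/generate_gofr.R <output_dir>
(from the package source tree; the script documents every parameter).

Any user-supplied library in the same format can be passed to
theory_input(gofr = read_gofr_library(dir)).
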