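#' Langevin dynamics parameters
#'
#' Defaults follow the production protocol of the coarse-grained model:
#' 1 ps timestep, friction 1/ps, 298 K. Masses are not part of that
#' protocol; equilibrium observables (cluster statistics, g(r)) do not
#' depend on them, while absolute diffusion coefficients do. The default
#' `mass_model = "volume_density"` assigns each species the mass of its
#' sphere at 1.35 g/cm^3 (a typical macromolecular density); `"unit"` sets
#' all masses to 1 kg/mol for property tests.
#'
#' @param timestep_ps Integration timestep, ps (> 0).
#' @param friction_per_ps Langevin friction, 1/ps (> 0).
#' @param temperature_K Thermostat temperature, K.
#' @param n_steps Number of steps (must be a multiple of
#'   `save_interval_steps`).
#' @param save_interval_steps Save a frame every this many steps.
#' @param seed Integer RNG seed for the thermostat noise.
#' @param mass_model `"volume_density"` or `"unit"`.
#' @return An object of class `"simulation_params"`.
#' @export
simulation_params <- function(timestep_ps = 1, friction_per_ps = 1,
                              temperature_K = 298, n_steps = 100000L,
                              save_interval_steps = 1000L, seed = 1L,
                              mass_model = c("volume_density", "unit")) {
  mass_model <- match.arg(mass_model)
  stopifnot(timestep_ps > 0, friction_per_ps > 0, temperature_K > 0,
            n_steps >= 1, save_interval_steps >= 1,
            n_steps %% save_interval_steps == 0)
  structure(list(
    timestep_ps = timestep_ps, friction_per_ps = friction_per_ps,
    temperature_K = temperature_K, n_steps = as.integer(n_steps),
    save_interval_steps = as.integer(save_interval_steps),
    seed = as.integer(seed), mass_model = mass_model
  ), class = "simulation_params")
}

# per-species masses in g/mol (the consistent mass unit for kJ/mol, nm, ps)
species_masses <- function(spec, mass_model) {
  if (mass_model == "unit") return(rep(1, length(spec$species)))
  vol_nm3 <- vapply(spec$species, function(s) (4 / 3) * pi * s$radius_nm^3,
                    numeric(1))
  # sphere volume at 1.35 g/cm^3 = 1.35e-21 g/nm^3, per mole of particles
  vol_nm3 * 1.35e-21 * cg_constants$NA_mol
}

#' Run Langevin dynamics for a system
#'
#' Integrates the Langevin equation with the coarse-grained pair potential
#' using a BAOAB splitting in a cubic periodic box. Deterministic for a
#' fixed seed on a fixed platform. Frames are wrapped into `[0, box)`.
#'
#' @param spec A [system_spec()].
#' @param coords Starting N x 3 coordinates (nm), e.g. from
#'   [random_placement()]. If `NULL`, [random_placement()] is called with
#'   the simulation seed.
#' @param params A [simulation_params()]. Its `temperature_K` overrides the
#'   spec temperature for the thermostat.
#' @param save_first Save the starting configuration as frame 1.
#' @return An object of class `"cg_trajectory"`: list with `frames`
#'   (N x 3 x n_frames array, nm), `times_ns`, `species_index`,
#'   `species_names`, `box_nm`, `spec`, diagnostics (`potential_kJmol`,
#'   `kinetic_kJmol` per frame), `final_coords`, and provenance
#'   (`seed`, `mass_model`, flag that dynamics are mass-convention
#'   dependent).
#' @export
run_simulation <- function(spec, coords = NULL, params = simulation_params(),
                           save_first = TRUE) {
  stopifnot(inherits(spec, "system_spec"), inherits(params, "simulation_params"))
  if (is.null(coords)) coords <- random_placement(spec, seed = params$seed)
  idx <- spec_species_index(spec)
  stopifnot(nrow(coords) == length(idx), ncol(coords) == 3)
  tabs <- spec_pair_tables(spec)
  masses <- species_masses(spec, params$mass_model)
  kT <- cg_constants$kB * params$temperature_K
  res <- cpp_run_langevin(
    coords, as.integer(idx - 1L), tabs$sigma_ij, tabs$A_ij,
    spec$params$epsilon_kJmol, spec$params$A0_kJmol, spec$params$kappa,
    spec$params$cutoff_nm, spec$params$switch_on_nm, spec$box_nm,
    masses, kT, params$friction_per_ps, params$timestep_ps,
    params$n_steps, params$save_interval_steps, params$seed, save_first)
  structure(list(
    frames = res$frames,
    times_ns = res$times_ps / 1000,
    species_index = idx,
    species_names = vapply(spec$species, function(s) s$name, character(1)),
    box_nm = spec$box_nm,
    spec = spec,
    potential_kJmol = res$potential_kJmol,
    kinetic_kJmol = res$kinetic_kJmol,
    final_coords = res$final_coords,
    provenance = list(
      seed = params$seed, mass_model = params$mass_model,
      timestep_ps = params$timestep_ps,
      friction_per_ps = params$friction_per_ps,
      temperature_K = params$temperature_K,
      n_steps = params$n_steps,
      note = "dynamic observables (D_tr) depend on the mass convention"
    )
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat(sprintf("<cg_trajectory> %d particles, %d frames, %.3f ns span, box %.2f nm\n",
              dim(x$frames)[1], nf, diff(range(x$times_ns)), x$box_nm))
  cat(sprintf("  species: %s\n", paste(x$species_names, collapse = ", ")))
  cat(sprintf("  <U> = %.2f kJ/mol, <K> = %.2f kJ/mol (per system)\n",
              mean(x$potential_kJmol), mean(x$kinetic_kJmol)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame of a trajectory
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @return N x 3 coordinate matrix (nm).
#' @export
get_frame <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Total potential energy of a configuration
#'
#' Sum over all pairs of the coarse-grained pair potential under the
#' minimum-image convention (matches an all-pairs brute-force evaluation
#' exactly).
#'
#' @param frame N x 3 coordinate matrix, nm.
#' @param spec A [system_spec()].
#' @return Energy in kJ/mol.
#' @export
potential_energy <- function(frame, spec) {
  idx <- spec_species_index(spec)
  if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  stopifnot(nrow(frame) == length(idx))
  tabs <- spec_pair_tables(spec)
  cpp_potential_energy(frame, as.integer(idx - 1L), tabs$sigma_ij, tabs$A_ij,
                       spec$params$epsilon_kJmol, spec$params$A0_kJmol,
                       spec$params$kappa, spec$params$cutoff_nm,
                       spec$params$switch_on_nm, spec$box_nm)
}
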