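test_that("potential energy matches a direct R transcription and cutoff contract", {
  p <- interaction_params(kappa = 0.7, cutoff_nm = 12, switch_on_nm = 11.5,
                          charge_model = "eq5")
  spec <- system_spec(30, list(species("RNA", 1.47, -46, count = 1,
                                       charge_model = "eq5"),
                               species("trypsin", 1.81, 6, count = 1,
                                       charge_model = "eq5")),
                      p, allow_reduced_cutoff = TRUE)
  # single particle
  solo <- system_spec(30, list(species("A", 1.5, 0, count = 1)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  expect_identical(potential_energy(matrix(c(1, 1, 1), 1), solo), 0)
  # two particles inside the switch region: direct transcription oracle
  tabs <- coacerv:::spec_pair_tables(spec)
  for (r in c(2.8, 3.35, 5, 9)) {
    fr <- rbind(c(5, 5, 5), c(5 + r, 5, 5))
    expect_equal(potential_energy(fr, spec),
                 oracle_pair_energy(r, tabs$sigma_ij[1, 2], tabs$A_ij[1, 2],
                                    kappa = 0.7),
                 tolerance = 1e-12)
  }
  # beyond the cutoff the pair contributes exactly zero
  fr <- rbind(c(1, 1, 1), c(14, 1, 1))
  expect_identical(potential_energy(fr, spec), 0)
  # minimum image: particles across the periodic boundary interact
  fr <- rbind(c(0.5, 5, 5), c(29.5, 5, 5))  # 1 nm apart through the wall
  expect_gt(potential_energy(fr, spec), 10)
})

test_that("energies and forces agree between engine and frame evaluation", {
  spec <- desk_binary("trypsin", box_nm = 40)
  co <- random_placement(spec, seed = 3)
  u1 <- potential_energy(co, spec)
  sp <- simulation_params(n_steps = 10, save_interval_steps = 10, seed = 1)
  tr <- run_simulation(spec, co, sp, save_first = TRUE)
  expect_equal(tr$potential_kJmol[1], u1, tolerance = 1e-10)
})

test_that("simulations are deterministic under a fixed seed", {
  spec <- desk_binary("trypsin", box_nm = 40)
  co <- random_placement(spec, seed = 3)
  sp <- simulation_params(n_steps = 2000, save_interval_steps = 500, seed = 7)
  t1 <- run_simulation(spec, co, sp)
  t2 <- run_simulation(spec, co, sp)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_simulation(spec, co, simulation_params(n_steps = 2000,
                                                   save_interval_steps = 500,
                                                   seed = 8))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("near-ideal gas satisfies equipartition within 2%", {
  p <- interaction_params(epsilon_kJmol = 1e-12, A0_kJmol = 0)
  spec <- system_spec(40, list(species("CRW", 2.52, 0, count = 60)), p,
                      temperature_K = 298, allow_reduced_cutoff = TRUE)
  co <- random_placement(spec, seed = 2)
  sp <- simulation_params(n_steps = 20000, save_interval_steps = 200,
                          seed = 5)
  tr <- run_simulation(spec, co, sp)
  kT <- coacerv::cg_constants$kB * 298
  expect_equal(mean(tr$kinetic_kJmol[-(1:10)]), 1.5 * 60 * kT,
               tolerance = 0.02)
})

test_that("free-particle diffusion recovers kB T / (m gamma) within 5%", {
  spec <- system_spec(200, list(species("RNA", 1.47, -46, count = 1)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  sp <- simulation_params(n_steps = 1000000, save_interval_steps = 200,
                          seed = 11)
  tr <- run_simulation(spec, matrix(100, 1, 3), sp)
  m <- coacerv:::species_masses(spec, "volume_density")
  kT <- coacerv::cg_constants$kB * 298
  D_expect <- kT / (m * 1) * 1e6  # nm^2/ps -> nm^2/us
  msd_res <- msd(tr)
  D_fit <- fit_diffusion(msd_res, tau_max_ns = 50)
  expect_equal(as.numeric(D_fit), as.numeric(D_expect), tolerance = 0.05)
})

test_that("a strongly bound pair samples distances near the potential minimum", {
  p <- interaction_params(kappa = 1.0, cutoff_nm = 6, switch_on_nm = 5.5,
                          charge_model = "eq5")
  spec <- system_spec(12, list(species("RNA", 1.47, -46, count = 1,
                                       charge_model = "eq5"),
                               species("POS", 1.81, 100, count = 1,
                                       charge_model = "eq5")),
                      p, allow_reduced_cutoff = TRUE)
  tabs <- coacerv:::spec_pair_tables(spec)
  u_of <- function(r) pair_potential(r, tabs$sigma_ij[1, 2], tabs$A_ij[1, 2], spec$params)
  r_min <- stats::optimize(u_of, c(2, 8))$minimum
  co <- rbind(c(6, 6, 6), c(6 + r_min, 6, 6))
  sp <- simulation_params(n_steps = 400000, save_interval_steps = 100,
                          seed = 3)
  tr <- run_simulation(spec, co, sp)
  d <- vapply(seq_len(n_frames(tr)), function(f) {
    fr <- get_frame(tr, f)
    dd <- fr[1, ] - fr[2, ]
    dd <- dd - spec$box_nm * round(dd / spec$box_nm)
    sqrt(sum(dd^2))
  }, numeric(1))
  peak <- as.numeric(names(which.max(table(round(d[-(1:100)], 1)))))
  expect_lt(abs(peak - r_min) / r_min, 0.10)
})

test_that("two-particle sampling reproduces the Boltzmann r-distribution (KS)", {
  p <- interaction_params(kappa = 0.7, cutoff_nm = 6, switch_on_nm = 5.5,
                          charge_model = "eq5")
  spec <- system_spec(12, list(species("RNA", 1.47, -46, count = 1,
                                       charge_model = "eq5"),
                               species("POS", 1.81, 12, count = 1,
                                       charge_model = "eq5")),
                      p, temperature_K = 298, allow_reduced_cutoff = TRUE)
  co <- rbind(c(6, 6, 6), c(9.5, 6, 6))
  sp <- simulation_params(n_steps = 2000000, save_interval_steps = 20,
                          seed = 13)
  tr <- run_simulation(spec, co, sp, save_first = FALSE)
  box <- spec$box_nm
  d <- sqrt(colSums((apply(tr$frames[1, , ] - tr$frames[2, , ], 2,
                           function(v) v - box * round(v / box)))^2))
  d <- d[-(1:5000)]                       # discard equilibration
  d <- d[d < box / 2]                     # sphere where p(r) ~ r^2 e^(-U/kT)
  tabs <- coacerv:::spec_pair_tables(spec)
  kT <- coacerv::cg_constants$kB * 298
  rr <- seq(1e-3, box / 2, length.out = 4000)
  w <- rr^2 * exp(-pair_potential(rr, tabs$sigma_ij[1, 2], tabs$A_ij[1, 2],
                                  spec$params) / kT)
  cdf_th <- cumsum(w) / sum(w)
  cdf_at <- stats::approxfun(rr, cdf_th, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(d, cdf_at))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("overlapping start configurations are reported as force overflow", {
  spec <- system_spec(30, list(species("A", 2, 0, count = 2)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  co <- rbind(c(5, 5, 5), c(5 + 1e-7, 5, 5))
  expect_error(run_simulation(spec, co, simulation_params(n_steps = 10,
                                                          save_interval_steps = 10)),
               "overflow|overlap")
})
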