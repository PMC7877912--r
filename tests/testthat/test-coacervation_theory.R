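test_that("interaction integrals: quadrature oracle, identity scaling, null potential", {
  lib <- flat_gofr_library(1)
  inp <- theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.45, c_P_mM = 0.35,
                      gofr = lib)
  # fine-grid trapezoid oracle for ghat == 1 and a pure screened-charge
  # term (the hard LJ core is excluded by g = 0 in real tables; a flat
  # table needs it switched off for the integral to be finite)
  inp$params$epsilon_kJmol <- 1e-300
  r <- seq(1e-6, 100, length.out = 400001)
  u <- pair_potential(r, inp$sigma[["RP"]], inp$A_pair[["RP"]], inp$params)
  oracle <- 2 * pi * sum(diff(r) * (u[-1] * r[-1]^2 + u[-length(r)] * r[-length(r)]^2) / 2)
  x_rp <- interaction_integral_x(inp, "RP", "condensed")
  expect_equal(x_rp, oracle, tolerance = 1e-6)
  # identical source radii: scaling ratio 1 leaves the integral unchanged
  inp_same <- theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.45,
                           c_P_mM = 0.35, q_R = -46, r_R_nm = 1.47,
                           gofr = lib)
  expect_equal(interaction_integral_x(inp_same, "RR", "dilute"),
               interaction_integral_x(inp_same, "RR", "condensed"))
  # a vanishing potential gives a vanishing integral
  inp0 <- inp
  inp0$params$epsilon_kJmol <- 1e-300
  inp0$params$A0_kJmol <- 0
  inp0$A_pair <- c(RR = 0, RP = 0, PP = 0)
  expect_lt(abs(interaction_integral_x(inp0, "RP", "condensed")), 1e-200)
})

test_that("chemical potentials: entropy-only closed forms", {
  lib <- flat_gofr_library(1)
  inp <- theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.4, c_P_mM = 0.4,
                      gofr = lib)
  inp$x <- lapply(inp$x, function(...) 0)  # switch off enthalpies
  Rg <- coacerv::cg_constants$R_gas
  # at the total density the entropy change is zero
  expect_equal(chemical_potential(inp, "R", "dilute", inp$rho_R, inp$rho_P), 0,
               tolerance = 1e-12)
  # at half the total density mu = -T R log 2
  expect_equal(chemical_potential(inp, "R", "dilute", inp$rho_R / 2, inp$rho_P),
               -298 * Rg * log(2), tolerance = 1e-12)
  # condensed-phase packing factor reduces the entropy at equal density
  mu_c <- chemical_potential(inp, "R", "condensed", inp$rho_R, inp$rho_P)
  expect_gt(mu_c, 0)
  expect_true(is.nan(chemical_potential(inp, "R", "dilute", 0, inp$rho_P)))
})

test_that("returned solutions conserve mass and satisfy their stationarity", {
  lib <- packaged_gofr()
  cases <- list(c(6, 1.81), c(8, 1.54), c(2, 1.64))
  for (cs in cases) {
    inp <- theory_input(q_P = cs[1], r_P_nm = cs[2], c_R_mM = 0.45,
                        c_P_mM = 0.35, gofr = lib)
    sol <- suppressWarnings(solve_coexistence(inp, n_vc = 80L, n_inner = 60L))
    # mass conservation per species to 1e-10 relative
    lhs_R <- (1 - sol$Vc) * sol$rho_R_dilute + sol$Vc * sol$rho_R_condensed
    lhs_P <- (1 - sol$Vc) * sol$rho_P_dilute + sol$Vc * sol$rho_P_condensed
    expect_equal(lhs_R, inp$rho_R, tolerance = 1e-10)
    expect_equal(lhs_P, inp$rho_P, tolerance = 1e-10)
    if (sol$phase_separated) {
      expect_lt(sol$packing, inp$max_packing * (1 + 1e-6))
      if (sol$at_packing_limit) {
        expect_lt(sol$kkt_residual, 1e-8)
      } else {
        expect_lt(max(sol$residuals, na.rm = TRUE), 1e-8)
      }
      # condensed phase is the dense one
      expect_gt(sol$rho_R_condensed, sol$rho_R_dilute)
    }
    # the winning scenario has the lowest evaluated free energy
    expect_equal(sol$dG, min(sol$dG_scenarios, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("phase separation strengthens with protein charge", {
  lib <- packaged_gofr()
  try_sol <- suppressWarnings(solve_coexistence(
    theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.45, c_P_mM = 0.35,
                 gofr = lib), n_vc = 80L, n_inner = 60L))
  expect_true(try_sol$phase_separated)
  expect_gt(try_sol$c_R_condensed_mM, 1)     # mM-scale condensate
  myo_sol <- suppressWarnings(solve_coexistence(
    theory_input(q_P = 2, r_P_nm = 1.64, c_R_mM = 0.45, c_P_mM = 0.35,
                 gofr = lib), n_vc = 80L, n_inner = 60L))
  # the free-energy drive toward coexistence grows with the charge product
  margin <- function(sol) sol$dG_scenarios[["disperse"]] -
    sol$dG_scenarios[["both-coexist"]]
  expect_gt(margin(try_sol), margin(myo_sol))
})

test_that("negatively charged proteins never phase separate with RNA", {
  lib <- packaged_gofr()
  # like-charge pairs carry no attractive screened-electrostatic term
  inp_neg <- theory_input(q_P = -10, r_P_nm = 2.5, c_R_mM = 0.45,
                          c_P_mM = 0.35, gofr = lib)
  expect_gte(inp_neg$A_pair[["RP"]], 0)
  # small neutral particles stay disperse
  neu_small <- suppressWarnings(solve_coexistence(
    theory_input(q_P = 0, r_P_nm = 1.5, q_R = 0, c_R_mM = 0.45,
                 c_P_mM = 0.35, gofr = lib), n_vc = 60L, n_inner = 40L))
  expect_identical(neu_small$scenario, 1L)
  # the clearly negative part of the charge plane is uniformly disperse
  qs <- seq(-20, -5, length.out = 10)
  rs <- seq(1.2, 3.5, length.out = 10)
  map <- suppressWarnings(scan_charge_radius(qs, rs, gofr = lib,
                                             n_vc = 40L, n_inner = 30L))
  expect_identical(nrow(map), 100L)
  expect_false(any(map$ps))
})

test_that("BSA-like negative protein stays disperse at the standard conditions", {
  lib <- packaged_gofr()
  sol <- suppressWarnings(solve_coexistence(
    theory_input(q_P = -17, r_P_nm = 2.58, c_R_mM = 0.45, c_P_mM = 0.35,
                 gofr = lib), n_vc = 80L, n_inner = 60L))
  expect_false(sol$phase_separated)
})

test_that("concentration scan: protein-free column never separates; reentrance", {
  lib <- packaged_gofr()
  inp <- theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.1, c_P_mM = 0.15,
                      gofr = lib)
  # a minimum protein concentration is required for PS
  lo <- suppressWarnings(solve_coexistence(
    update_theory_input(inp, c_P_mM = 0.05), n_vc = 80L, n_inner = 60L))
  hi <- suppressWarnings(solve_coexistence(
    update_theory_input(inp, c_R_mM = 0.45, c_P_mM = 0.35),
    n_vc = 80L, n_inner = 60L))
  expect_false(lo$phase_separated)
  expect_true(hi$phase_separated)
  # reentrance: excess RNA dissolves the condensates again
  grid <- suppressWarnings(scan_concentration(
    inp, c_R_grid_mM = c(0.45, 20), c_P_grid_mM = 0.35,
    n_vc = 60L, n_inner = 40L))
  expect_true(grid$ps[grid$c_R_mM == 0.45])
  expect_false(grid$ps[grid$c_R_mM == 20])
})

test_that("temperature scan: PS vanishes at high T and solutions sit at the cap", {
  lib <- packaged_gofr()
  inp <- theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.45, c_P_mM = 0.35,
                      gofr = lib)
  sc <- suppressWarnings(scan_temperature(inp, c(280, 298, 350, 500, 1500, 6000),
                                          n_vc = 60L, n_inner = 40L))
  per <- sc$per_T
  expect_true(per$ps[per$T_K == 298])
  expect_false(per$ps[per$T_K == 6000])
  # once lost with rising T, PS does not reappear on the grid
  flips <- diff(per$ps)
  expect_lte(sum(flips == 1), 0)
  expect_true(is.finite(sc$T_max_ps_K))
  # at low temperature the packing constraint binds
  expect_equal(per$packing[per$T_K == 280], 0.3, tolerance = 1e-6)
})

test_that("PS flags are robust to the packing cap around the default", {
  lib <- packaged_gofr()
  for (cap in c(0.3, 0.35, 0.4)) {
    s_try <- suppressWarnings(solve_coexistence(
      theory_input(q_P = 6, r_P_nm = 1.81, c_R_mM = 0.45, c_P_mM = 0.35,
                   max_packing = cap, gofr = lib), n_vc = 60L, n_inner = 40L))
    expect_true(s_try$phase_separated)
    s_bsa <- suppressWarnings(solve_coexistence(
      theory_input(q_P = -17, r_P_nm = 2.58, c_R_mM = 0.45, c_P_mM = 0.35,
                   max_packing = cap, gofr = lib), n_vc = 60L, n_inner = 40L))
    expect_false(s_bsa$phase_separated)
  }
})

test_that("g(r) library round-trips through its text format", {
  lib <- flat_gofr_library(1.5)
  dir <- tempfile("gofr")
  write_gofr_library(lib, dir)
  back <- read_gofr_library(dir)
  expect_equal(back$r_R_MD, lib$r_R_MD)
  expect_equal(back$tables$RP$condensed$g, lib$tables$RP$condensed$g)
  unlink(dir, recursive = TRUE)
})
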