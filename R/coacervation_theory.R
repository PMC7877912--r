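# ---------------------------------------------------------------------------
# Analytical two-component coacervation theory.
#
# Chemical potentials mu = dh - T ds per phase, with enthalpies from the
# coarse-grained pair potential convolved with phase-specific radial
# distribution functions (x = 2 pi Int g(r) U(r) r^2 dr; the shared 2pi
# prefactor halves every pair interaction so each pair is counted once in
# the total free energy), and entropies from density ratios relative to the
# fully disperse system, with an excluded-volume correction in the condensed
# phase. Coexistence is found by scanning the condensed volume V_c and
# solving mu_d = mu_c with Newton-Raphson; the scenario (disperse,
# condensed, both coexist, R-only, P-only) with the lowest total free
# energy wins.
# ---------------------------------------------------------------------------

GOFR_PAIRS <- c("RR", "RP", "PP")
GOFR_PHASES <- c("dilute", "condensed", "disperse")

#' A library of radial distribution functions for the theory
#'
#' Holds tabulated, volume- and density-normalized g(r) curves for the
#' RR, RP and PP pairs in the dilute, condensed and disperse reference
#' phases, together with the particle radii of the source simulations
#' (`r_R_MD`, `r_P_MD`). Tables are truncated at `trunc_nm` and treated as
#' exactly 1 beyond it (removes finite-size artifacts); for particle sizes
#' other than the source sizes the radial axis is rescaled by the ratios
#' `r_R/r_R_MD` (RR), `r_P/r_P_MD` (PP) and `(r_R+r_P)/(r_R_MD+r_P_MD)`
#' (RP).
#'
#' @param tables Named list: for each of "RR", "RP", "PP" a named list of
#'   data.frames (columns `r_nm`, `g`) for phases "dilute", "condensed",
#'   "disperse".
#' @param r_R_MD,r_P_MD Source radii, nm.
#' @param trunc_nm Truncation radius, nm (default 20).
#' @return An object of class `"gofr_library"`.
#' @export
gofr_library <- function(tables, r_R_MD, r_P_MD, trunc_nm = 20) {
  stopifnot(r_R_MD > 0, r_P_MD > 0, trunc_nm > 0)
  for (p in GOFR_PAIRS) {
    if (is.null(tables[[p]])) stop(sprintf("missing pair table '%s'", p))
    for (ph in GOFR_PHASES) {
      tb <- tables[[p]][[ph]]
      if (is.null(tb)) stop(sprintf("missing g(r) table %s/%s", p, ph))
      if (!all(c("r_nm", "g") %in% names(tb))) stop("tables need r_nm and g")
      if (any(tb$g < 0) || any(diff(tb$r_nm) <= 0)) {
        stop(sprintf("invalid g(r) table %s/%s", p, ph))
      }
    }
  }
  structure(list(tables = tables, r_R_MD = r_R_MD, r_P_MD = r_P_MD,
                 trunc_nm = trunc_nm), class = "gofr_library")
}

#' @export
print.gofr_library <- function(x, ...) {
  cat(sprintf("<gofr_library> source radii r_R = %.2f nm, r_P = %.2f nm; truncated at %g nm\n",
              x$r_R_MD, x$r_P_MD, x$trunc_nm))
  invisible(x)
}

#' Write / read a g(r) library as delimited text plus a JSON sidecar
#'
#' One TSV per pair/phase (`<pair>_<phase>.tsv`, columns `r_nm`, `g`) and a
#' `library.json` naming the source radii and truncation radius.
#'
#' @param lib A [gofr_library()].
#' @param dir Directory to write to / read from.
#' @return `write_gofr_library` returns `dir` invisibly;
#'   `read_gofr_library` returns a [gofr_library()].
#' @export
write_gofr_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in GOFR_PAIRS) for (ph in GOFR_PHASES) {
    utils::write.table(lib$tables[[p]][[ph]],
                       file.path(dir, sprintf("%s_%s.tsv", p, ph)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(r_R_MD = lib$r_R_MD, r_P_MD = lib$r_P_MD, trunc_nm = lib$trunc_nm),
    file.path(dir, "library.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_gofr_library
#' @export
read_gofr_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "library.json"))
  tables <- list()
  for (p in GOFR_PAIRS) {
    tables[[p]] <- list()
    for (ph in GOFR_PHASES) {
      tables[[p]][[ph]] <- utils::read.table(
        file.path(dir, sprintf("%s_%s.tsv", p, ph)),
        header = TRUE, sep = "\t")
    }
  }
  gofr_library(tables, meta$r_R_MD, meta$r_P_MD, meta$trunc_nm)
}

#' Reference g(r) library shipped with the package
#'
#' Tables generated by the package's own Langevin simulator for a binary
#' RNA-trypsin-sized system (source radii r_R = 1.47 nm, r_P = 1.81 nm;
#' generation script and seeds in `inst/extdata/gofr/README`). Any
#' user-supplied [gofr_library()] can be used instead.
#'
#' @return A [gofr_library()].
#' @export
default_gofr_library <- function() {
  dir <- system.file("extdata", "gofr", package = "coacerv")
  if (!nzchar(dir)) stop("packaged g(r) library not found")
  read_gofr_library(dir)
}

#' Input set for the coacervation theory
#'
#' Charges are nominal; effective charges and long-range coefficients are
#' derived with the selected charge model (the theory default is the
#' square-root form, `"eq6"`, with a screening factor kappa = 1.17).
#'
#' @param q_P,r_P_nm Protein nominal charge (e) and radius (nm).
#' @param c_R_mM,c_P_mM Total RNA and protein concentrations, mM.
#' @param q_R,r_R_nm RNA nominal charge and radius (defaults: J345 RNA,
#'   q = -46, r = 1.47 nm).
#' @param T_K Temperature, K.
#' @param kappa Screening factor for the theory potential (default 1.17).
#' @param max_packing Maximum combined macromolecular volume fraction in
#'   the condensed phase (default 0.3; similar results for 0.2-0.4).
#' @param gofr A [gofr_library()] (default: the packaged one).
#' @param r_max_nm Upper integration limit for the enthalpy integrals, nm.
#' @param charge_model,log_base Effective-charge model (see
#'   [effective_charge()]).
#' @return An object of class `"theory_input"` with the interaction
#'   integrals `x` precomputed (independent of concentrations and T).
#' @export
theory_input <- function(q_P, r_P_nm, c_R_mM, c_P_mM,
                         q_R = -46, r_R_nm = 1.47,
                         T_K = 298, kappa = 1.17, max_packing = 0.3,
                         gofr = default_gofr_library(), r_max_nm = 100,
                         charge_model = c("eq6", "eq5"),
                         log_base = c("natural", "decadic")) {
  charge_model <- match.arg(charge_model)
  log_base <- match.arg(log_base)
  stopifnot(r_P_nm > 0, r_R_nm > 0, c_R_mM >= 0, c_P_mM >= 0, T_K > 0,
            kappa > 0, max_packing > 0, max_packing < 1)
  params <- interaction_params(kappa = kappa, charge_model = charge_model,
                               log_base = log_base)
  A_R <- a_coefficient(effective_charge(q_R, charge_model, log_base))
  A_P <- a_coefficient(effective_charge(q_P, charge_model, log_base))
  sig_R <- sigma_from_radius(r_R_nm)
  sig_P <- sigma_from_radius(r_P_nm)
  inp <- structure(list(
    q_R = q_R, q_P = q_P, r_R_nm = r_R_nm, r_P_nm = r_P_nm,
    c_R_mM = c_R_mM, c_P_mM = c_P_mM,
    rho_R = mM_to_nm3(c_R_mM), rho_P = mM_to_nm3(c_P_mM),
    T_K = T_K, kappa = kappa, max_packing = max_packing,
    gofr = gofr, r_max_nm = r_max_nm,
    charge_model = charge_model, log_base = log_base,
    params = params,
    A_R = A_R, A_P = A_P,
    sigma = c(RR = 2 * sig_R, RP = sig_R + sig_P, PP = 2 * sig_P),
    A_pair = c(RR = A_R * A_R, RP = A_R * A_P, PP = A_P * A_P),
    V_R = (4 / 3) * pi * r_R_nm^3, V_P = (4 / 3) * pi * r_P_nm^3
  ), class = "theory_input")
  inp$x <- compute_all_x(inp)
  inp
}

#' @export
print.theory_input <- function(x, ...) {
  cat(sprintf("<theory_input> R: q = %+g, r = %.2f nm, c = %g mM | P: q = %+g, r = %.2f nm, c = %g mM\n",
              x$q_R, x$r_R_nm, x$c_R_mM, x$q_P, x$r_P_nm, x$c_P_mM))
  cat(sprintf("  T = %g K, kappa = %.2f, max packing %.2f, charges %s\n",
              x$T_K, x$kappa, x$max_packing, x$charge_model))
  invisible(x)
}

# interpolate a scaled, truncated g(r) at radii r (nm)
gofr_eval <- function(lib, pair, phase, ratio, r) {
  tb <- lib$tables[[pair]][[phase]]
  s <- r / ratio  # back to source scale
  g <- stats::approx(tb$r_nm, tb$g, xout = s, rule = 2)$y
  g[s > lib$trunc_nm | s > max(tb$r_nm)] <- 1  # uncorrelated beyond the table
  g
}

#' Interaction integral x for one pair and phase
#'
#' `x = 2 pi Int_0^{r_max} ghat(r) U(r) r^2 dr` with the pair potential for
#' the input's charges/radii and the library g(r) rescaled to the input
#' particle sizes. Composite Simpson quadrature on a fixed fine grid
#' (deterministic; relative error well below 1e-6 for these smooth
#' integrands).
#'
#' @param input A [theory_input()].
#' @param pair One of "RR", "RP", "PP".
#' @param phase One of "dilute", "condensed", "disperse".
#' @param n_grid Number of Simpson intervals (even; default 8000).
#' @return x in kJ/mol nm^3.
#' @export
interaction_integral_x <- function(input, pair = GOFR_PAIRS,
                                   phase = GOFR_PHASES, n_grid = 8000L) {
  pair <- match.arg(pair)
  phase <- match.arg(phase)
  lib <- input$gofr
  ratio <- switch(pair,
    RR = input$r_R_nm / lib$r_R_MD,
    PP = input$r_P_nm / lib$r_P_MD,
    RP = (input$r_R_nm + input$r_P_nm) / (lib$r_R_MD + lib$r_P_MD))
  if (n_grid %% 2 == 1) n_grid <- n_grid + 1L
  r <- seq(1e-6, input$r_max_nm, length.out = n_grid + 1L)
  g <- gofr_eval(lib, pair, phase, ratio, r)
  u <- pair_potential(r, input$sigma[[pair]], input$A_pair[[pair]],
                      input$params)
  f <- g * u * r^2
  f[g < 1e-12] <- 0  # inside the excluded core g = 0 suppresses the LJ wall
  h <- r[2] - r[1]
  w <- rep(c(4, 2), length.out = n_grid - 1L)
  integral <- h / 3 * (f[1] + f[n_grid + 1L] + sum(w * f[2:n_grid]))
  2 * pi * integral
}

compute_all_x <- function(input) {
  x <- list()
  for (ph in GOFR_PHASES) {
    for (p in GOFR_PAIRS) {
      x[[sprintf("%s_%s", substr(ph, 1, 1), p)]] <-
        interaction_integral_x(input, p, ph)
    }
  }
  x
}

#' Chemical potential of one species in one phase
#'
#' `mu = dh - T ds`, with `dh` linear in the phase densities through the
#' precomputed x integrals (the self-pair 1/2 factor is folded into x), and
#' `ds` the density-ratio entropy; the condensed phase carries the
#' excluded-volume factor `1 - (rho_Rc V_R + rho_Pc V_P)`.
#'
#' @param input A [theory_input()].
#' @param species_id `"R"` or `"P"`.
#' @param phase `"dilute"`, `"condensed"` or `"disperse"` (the latter uses
#'   the disperse-reference g(r) with no packing correction).
#' @param rho_R,rho_P Number densities in that phase, 1/nm^3 (vectorized).
#' @return mu in kJ/mol; `NaN` where the phase density of the species is 0
#'   (mu undefined; handled by the scenario logic).
#' @export
chemical_potential <- function(input, species_id = c("R", "P"),
                               phase = c("dilute", "condensed", "disperse"),
                               rho_R, rho_P) {
  species_id <- match.arg(species_id)
  phase <- match.arg(phase)
  x <- input$x
  TT <- input$T_K
  Rg <- cg_constants$R_gas
  pre <- substr(phase, 1, 1)
  rho_tot <- if (species_id == "R") input$rho_R else input$rho_P
  rho_self <- if (species_id == "R") rho_R else rho_P
  xs <- x[[sprintf("%s_%s", pre, if (species_id == "R") "RR" else "PP")]]
  xc <- x[[sprintf("%s_%s", pre, "RP")]]
  dh <- rho_self * xs +
    (if (species_id == "R") rho_P else rho_R) * xc
  if (phase == "condensed") {
    packfac <- 1 - (rho_R * input$V_R + rho_P * input$V_P)
    ds <- Rg * log((rho_tot / rho_self) * packfac)
  } else {
    ds <- Rg * log(rho_tot / rho_self)
  }
  mu <- dh - TT * ds
  mu[rho_self <= 0] <- NaN
  mu
}

# mixing entropy contribution R * V_ph * sum rho log(rho / rho_sum);
# zero-density species contribute 0 (x log x -> 0)
smix_term <- function(V_ph, rho_R, rho_P) {
  Rg <- cg_constants$R_gas
  tot <- rho_R + rho_P
  tR <- ifelse(rho_R > 0, rho_R * log(rho_R / tot), 0)
  tP <- ifelse(rho_P > 0, rho_P * log(rho_P / tot), 0)
  Rg * V_ph * (tR + tP)
}

# vectorized safeguarded Newton-Raphson: f takes and returns vectors.
# Non-finite residuals (infeasible region, e.g. condensed packing >= 1)
# push the iterate toward the upper bound, where the residual is defined.
nr_solve_vec <- function(f, x0, lower, upper, tol = 1e-12, maxit = 100L) {
  lower <- rep_len(lower, length(x0))
  upper <- rep_len(upper, length(x0))
  x <- pmin(pmax(x0, lower), upper)
  fx <- f(x)
  for (it in seq_len(maxit)) {
    bad <- !is.finite(fx)
    if (any(bad)) {
      x[bad] <- (x[bad] + upper[bad]) / 2
      fx <- f(x)
      bad <- !is.finite(fx)
    }
    if (all(bad | abs(fx) < tol)) break
    h <- pmax(abs(x) * 1e-7, 1e-12)
    fp <- (f(x + h) - f(x - h)) / (2 * h)
    step <- fx / fp
    step[!is.finite(step)] <- 0
    xn <- pmin(pmax(x - step, lower), upper)
    upd <- !bad & abs(fx) >= tol
    x[upd] <- xn[upd]
    fx <- f(x)
  }
  list(x = x, fval = fx, converged = is.finite(fx) & abs(fx) < tol)
}

# residual functions of the coexistence conditions; all arguments vectors.
# V = 1; condensed densities follow from mass conservation.
make_residuals <- function(input) {
  rho_R0 <- input$rho_R
  rho_P0 <- input$rho_P
  list(
    rho_c = function(rho_d, rho_tot, Vc) (rho_tot - (1 - Vc) * rho_d) / Vc,
    f_R = function(rho_Rd, rho_Pd, Vc) {
      rho_Rc <- (rho_R0 - (1 - Vc) * rho_Rd) / Vc
      rho_Pc <- (rho_P0 - (1 - Vc) * rho_Pd) / Vc
      mu_d <- chemical_potential(input, "R", "dilute", rho_Rd, rho_Pd)
      mu_c <- chemical_potential(input, "R", "condensed", rho_Rc, rho_Pc)
      out <- mu_d - mu_c
      out[rho_Rc <= 0 | rho_Pc < 0] <- NaN
      out
    },
    f_P = function(rho_Rd, rho_Pd, Vc) {
      rho_Rc <- (rho_R0 - (1 - Vc) * rho_Rd) / Vc
      rho_Pc <- (rho_P0 - (1 - Vc) * rho_Pd) / Vc
      mu_d <- chemical_potential(input, "P", "dilute", rho_Rd, rho_Pd)
      mu_c <- chemical_potential(input, "P", "condensed", rho_Rc, rho_Pc)
      out <- mu_d - mu_c
      out[rho_Pc <= 0 | rho_Rc < 0] <- NaN
      out
    }
  )
}

# Total two-phase free energy per unit system volume (V = 1). Valid for any
# mass-conserving candidate state; chemical-potential equality is NOT
# assumed. At coexistence it reduces to the published per-scenario
# expressions. Species absent from a phase contribute nothing.
g_total <- function(input, Vc, rho_Rd, rho_Pd, rho_Rc, rho_Pc) {
  TT <- input$T_K
  n <- max(length(Vc), length(rho_Rd), length(rho_Pd),
           length(rho_Rc), length(rho_Pc))
  Vc <- rep_len(Vc, n)
  rho_Rd <- rep_len(rho_Rd, n)
  rho_Pd <- rep_len(rho_Pd, n)
  rho_Rc <- rep_len(rho_Rc, n)
  rho_Pc <- rep_len(rho_Pc, n)
  term <- function(active, V_ph, rho_self, mu) {
    out <- ifelse(active, V_ph * rho_self * mu, 0)
    out
  }
  acc <- term(Vc < 1 & rho_Rd > 0, 1 - Vc, rho_Rd,
              chemical_potential(input, "R", "dilute", rho_Rd, rho_Pd)) +
    term(Vc < 1 & rho_Pd > 0, 1 - Vc, rho_Pd,
         chemical_potential(input, "P", "dilute", rho_Rd, rho_Pd)) +
    term(Vc > 0 & rho_Rc > 0, Vc, rho_Rc,
         chemical_potential(input, "R", "condensed", rho_Rc, rho_Pc)) +
    term(Vc > 0 & rho_Pc > 0, Vc, rho_Pc,
         chemical_potential(input, "P", "condensed", rho_Rc, rho_Pc))
  acc - TT * (smix_term(1 - Vc, rho_Rd, rho_Pd) +
              smix_term(Vc, rho_Rc, rho_Pc))
}

#' Solve the two-component coexistence problem
#'
#' Evaluates the five candidate states -- (1) fully disperse, (2) fully
#' condensed, (3) both species coexisting between dilute and condensed
#' phases, (4) only R coexisting (no P in the dilute phase), (5) only P
#' coexisting -- and returns the one with the lowest total free energy.
#'
#' Each coexistence scenario is a constrained minimization of the total
#' free energy over the condensed volume fraction `V_c` (log-spaced scan)
#' and the dilute densities, subject to the condensed-phase packing cap
#' (`max_packing`). Where the cap is slack the optimum satisfies the
#' chemical-potential equalities `mu_dilute = mu_condensed`, solved by
#' Newton-Raphson over an inner density scan; where the cap binds (the
#' usual case -- the model gains energy with density, so solutions
#' accumulate at the volume-fraction limit) the optimum lies on the
#' packing boundary and satisfies the corresponding KKT stationarity
#' instead, found by bounded 1-D minimization along the constraint with
#' Newton polishing. `at_packing_limit` and the residuals in the returned
#' object say which case applies.
#'
#' @param input A [theory_input()].
#' @param n_vc Number of V_c scan points (log-spaced between 1e-5 and 0.999).
#' @param n_inner Inner density-scan points for the interior root search.
#' @param nr_tol Newton-Raphson tolerance on the equality residuals.
#' @param max_iter Newton-Raphson iteration cap.
#' @return An object of class `"theory_solution"`: scenario id and label,
#'   `phase_separated` flag, phase densities (1/nm^3) and mM equivalents,
#'   `Vc`, `dG` (total free energy of the returned state) and `dG_scenarios`
#'   (best per scenario), chemical potentials, `residuals` (mu-equality
#'   residuals where applicable), `at_packing_limit`, `kkt_residual`,
#'   `packing`, and the input.
#' @export
solve_coexistence <- function(input, n_vc = 400L, n_inner = 200L,
                              nr_tol = 1e-12, max_iter = 100L) {
  stopifnot(inherits(input, "theory_input"))
  TT <- input$T_K
  rho_R0 <- input$rho_R
  rho_P0 <- input$rho_P
  cap <- input$max_packing
  V_R <- input$V_R
  V_P <- input$V_P
  res <- make_residuals(input)
  packing <- function(rR, rP) rR * V_R + rP * V_P
  eps_lo <- 1e-12
  gscale <- TT * cg_constants$R_gas * max(rho_R0 + rho_P0, 1e-30)

  cand <- list()
  add_cand <- function(scenario, Vc, rRd, rPd, rRc, rPc,
                       resid = c(R = NA_real_, P = NA_real_),
                       at_limit = FALSE, kkt = NA_real_) {
    dg <- g_total(input, Vc, rRd, rPd, rRc, rPc)
    if (!is.finite(dg)) return(invisible(NULL))
    cand[[length(cand) + 1]] <<- list(
      scenario = scenario, dG = dg, Vc = Vc,
      rho_Rd = rRd, rho_Pd = rPd, rho_Rc = rRc, rho_Pc = rPc,
      resid = resid, at_limit = at_limit, kkt = kkt)
    invisible(NULL)
  }

  ## scenario 1: fully disperse (always feasible; reference state)
  mu_Rdis <- if (rho_R0 > 0)
    chemical_potential(input, "R", "disperse", rho_R0, rho_P0) else 0
  mu_Pdis <- if (rho_P0 > 0)
    chemical_potential(input, "P", "disperse", rho_R0, rho_P0) else 0
  dG1 <- rho_R0 * mu_Rdis + rho_P0 * mu_Pdis -
    TT * smix_term(1, rho_R0, rho_P0)
  cand[[1]] <- list(scenario = 1L, dG = dG1, Vc = 0,
                    rho_Rd = rho_R0, rho_Pd = rho_P0, rho_Rc = 0, rho_Pc = 0,
                    resid = c(R = NA_real_, P = NA_real_),
                    at_limit = FALSE, kkt = NA_real_)

  ## scenario 2: fully condensed (V_c = V)
  if (packing(rho_R0, rho_P0) < cap) {
    add_cand(2L, 1, 0, 0, rho_R0, rho_P0)
  }

  vc_grid <- exp(seq(log(1e-5), log(0.999), length.out = n_vc))

  ## ---- scenarios 4 and 5: one species confined to the condensate ----
  if (rho_R0 > 0 && rho_P0 > 0) {
    for (swap in c(FALSE, TRUE)) {
      # swap = FALSE: R coexists, all P condensed (scenario 4); TRUE: mirror
      scen_id <- if (swap) 5L else 4L
      rho_S0 <- if (swap) rho_P0 else rho_R0
      rho_O0 <- if (swap) rho_R0 else rho_P0
      V_S <- if (swap) V_P else V_R
      V_O <- if (swap) V_R else V_P
      fres <- if (swap) res$f_P else res$f_R

      # interior roots: f_S = 0 along the V_c grid
      fv <- function(x) {
        if (swap) fres(rep(0, length(x)), x, vc_grid)
        else fres(x, rep(0, length(x)), vc_grid)
      }
      sol <- nr_solve_vec(fv, rep(rho_S0 * 0.5, n_vc), eps_lo,
                          rho_S0 * (1 - 1e-12), nr_tol, max_iter)
      rho_Sd <- sol$x
      rho_Sc <- (rho_S0 - (1 - vc_grid) * rho_Sd) / vc_grid
      rho_Oc <- rho_O0 / vc_grid
      pk <- rho_Sc * V_S + rho_Oc * V_O
      ok <- sol$converged & rho_Sc > rho_Sd & pk < cap
      if (any(ok)) {
        dg <- rep(Inf, n_vc)
        for (j in which(ok)) {
          dg[j] <- g_total(input, vc_grid[j],
                           if (swap) 0 else rho_Sd[j],
                           if (swap) rho_Sd[j] else 0,
                           if (swap) rho_Oc[j] else rho_Sc[j],
                           if (swap) rho_Sc[j] else rho_Oc[j])
        }
        j <- which.min(dg)
        if (is.finite(dg[j])) {
          add_cand(scen_id, vc_grid[j],
                   if (swap) 0 else rho_Sd[j], if (swap) rho_Sd[j] else 0,
                   if (swap) rho_Oc[j] else rho_Sc[j],
                   if (swap) rho_Sc[j] else rho_Oc[j],
                   resid = if (swap) c(R = NA_real_, P = abs(sol$fval[j]))
                           else c(R = abs(sol$fval[j]), P = NA_real_))
        }
      }

      # cap-bound branch: packing = cap fixes everything at given V_c
      g_of_vc <- function(vc) {
        rOc <- rho_O0 / vc
        rSc <- (cap - rOc * V_O) / V_S
        if (rSc <= 0) return(NA_real_)
        rSd <- (rho_S0 - vc * rSc) / (1 - vc)
        if (rSd <= 0 || rSd >= rSc) return(NA_real_)
        g_total(input, vc,
                if (swap) 0 else rSd, if (swap) rSd else 0,
                if (swap) rOc else rSc, if (swap) rSc else rOc)
      }
      gb <- vapply(vc_grid, g_of_vc, numeric(1))
      if (any(is.finite(gb))) {
        j <- which.min(gb)
        lo <- vc_grid[max(1, j - 1)]
        hi <- vc_grid[min(n_vc, j + 1)]
        op <- stats::optimize(function(v) {
          g <- g_of_vc(v)
          if (is.finite(g)) g else Inf
        }, c(lo, hi), tol = 1e-14)
        vc_b <- op$minimum
        kkt <- Inf
        g0 <- g_of_vc(vc_b)
        for (np in 1:10) {
          h <- vc_b * 1e-6
          gp <- g_of_vc(vc_b + h)
          gm <- g_of_vc(vc_b - h)
          g0 <- g_of_vc(vc_b)
          if (!all(is.finite(c(gp, gm, g0)))) break
          d1 <- (gp - gm) / (2 * h)
          kkt <- abs(d1) * vc_b / gscale
          if (kkt < 1e-10) break
          d2 <- (gp - 2 * g0 + gm) / h^2
          step <- d1 / d2
          if (!is.finite(step) || d2 <= 0) break
          vc_b <- min(max(vc_b - step, lo), hi)
        }
        rOc <- rho_O0 / vc_b
        rSc <- (cap - rOc * V_O) / V_S
        rSd <- (rho_S0 - vc_b * rSc) / (1 - vc_b)
        if (is.finite(g0) && rSc > 0 && rSd > 0 && rSd < rSc) {
          add_cand(scen_id, vc_b,
                   if (swap) 0 else rSd, if (swap) rSd else 0,
                   if (swap) rOc else rSc, if (swap) rSc else rOc,
                   at_limit = TRUE, kkt = kkt)
        }
      }
    }

    ## ---- scenario 3: both species coexist ----
    best3 <- NULL
    note3 <- function(Vc, rRd, rPd, resid, at_limit, kkt) {
      rRc <- (rho_R0 - (1 - Vc) * rRd) / Vc
      rPc <- (rho_P0 - (1 - Vc) * rPd) / Vc
      if (rRc <= rRd || rPc <= rPd || rRc <= 0 || rPc <= 0) return(NULL)
      if (packing(rRc, rPc) >= cap * (1 + 1e-9)) return(NULL)
      dg <- g_total(input, Vc, rRd, rPd, rRc, rPc)
      if (!is.finite(dg)) return(NULL)
      if (is.null(best3) || dg < best3$dG) {
        best3 <<- list(scenario = 3L, dG = dg, Vc = Vc,
                       rho_Rd = rRd, rho_Pd = rPd,
                       rho_Rc = rRc, rho_Pc = rPc,
                       resid = resid, at_limit = at_limit, kkt = kkt)
      }
      NULL
    }

    pd_upper <- rho_P0 * (1 - 1e-12)
    # boundary curve at fixed Vc: rho_Pd as a function of rho_Rd such that
    # the condensed packing equals the cap
    bnd_rPd <- function(rRd, vc) {
      rRc <- (rho_R0 - (1 - vc) * rRd) / vc
      rPc <- (cap - rRc * V_R) / V_P
      (rho_P0 - vc * rPc) / (1 - vc)
    }
    g_bnd <- function(rRd, vc) {
      rPd <- bnd_rPd(rRd, vc)
      rRc <- (rho_R0 - (1 - vc) * rRd) / vc
      rPc <- (cap - rRc * V_R) / V_P
      bad <- !is.finite(rPd) | rPd <= 0 | rPc <= 0 | rRc <= 0 |
        rRc <= rRd | rPc <= rPd
      g <- rep(NA_real_, length(rRd))
      if (any(!bad)) {
        g[!bad] <- g_total(input, vc, rRd[!bad], rPd[!bad],
                           rRc[!bad], rPc[!bad])
      }
      g[!is.finite(g)] <- NA_real_
      g
    }

    for (vc in vc_grid) {
      # interior joint roots: solve f_R = 0 for rho_Pd on an rho_Rd grid,
      # then bracket sign changes of f_P and bisect to self-consistency
      rRd_grid <- seq(rho_R0 * 1e-5, rho_R0 * (1 - 1e-9),
                      length.out = n_inner)
      solP <- nr_solve_vec(function(x) res$f_R(rRd_grid, x, vc),
                           rep(rho_P0 * 0.5, n_inner), eps_lo, pd_upper,
                           nr_tol, max_iter)
      hP <- res$f_P(rRd_grid, solP$x, vc)
      vi <- which(solP$converged & is.finite(hP))
      if (length(vi) >= 2) {
        sgn <- sign(hP[vi])
        flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
        for (fl in flips) {
          a <- rRd_grid[vi[fl]]
          b <- rRd_grid[vi[fl + 1]]
          ha <- hP[vi[fl]]
          pstart <- solP$x[vi[fl]]
          for (bis in 1:80) {
            m <- (a + b) / 2
            sp <- nr_solve_vec(function(x) res$f_R(m, x, vc),
                               pstart, eps_lo, pd_upper,
                               nr_tol, max_iter)
            pstart <- sp$x
            hm <- if (sp$converged) res$f_P(m, sp$x, vc) else NA_real_
            if (!is.finite(hm)) break
            if (abs(hm) < 1e-10 || (b - a) < 1e-15 * rho_R0) {
              fR_m <- res$f_R(m, sp$x, vc)
              note3(vc, m, sp$x, resid = c(R = abs(fR_m), P = abs(hm)),
                    at_limit = FALSE, kkt = NA_real_)
              break
            }
            if (sign(hm) == sign(ha)) { a <- m; ha <- hm } else b <- m
          }
        }
      }

      # cap-bound branch: 1-D minimization along the packing boundary
      lo <- rho_R0 * 1e-6
      hi <- rho_R0 * (1 - 1e-9)
      sgrid <- seq(lo, hi, length.out = 60)
      gv <- g_bnd(sgrid, vc)
      if (any(is.finite(gv))) {
        j <- which.min(gv)
        a <- sgrid[max(1, j - 1)]
        b <- sgrid[min(length(sgrid), j + 1)]
        op <- stats::optimize(function(r) {
          g <- g_bnd(r, vc)
          if (is.finite(g)) g else Inf
        }, c(a, b), tol = 1e-12)
        rstar <- op$minimum
        # Newton polish on the tangential derivative
        h <- rho_R0 * 1e-7
        kkt <- Inf
        for (np in 1:10) {
          gp <- g_bnd(rstar + h, vc)
          gm <- g_bnd(rstar - h, vc)
          g0 <- g_bnd(rstar, vc)
          if (!all(is.finite(c(gp, gm, g0)))) break
          d1 <- (gp - gm) / (2 * h)
          kkt <- abs(d1) * rho_R0 / gscale
          if (kkt < 1e-10) break
          d2 <- (gp - 2 * g0 + gm) / h^2
          step <- d1 / d2
          if (!is.finite(step) || d2 <= 0) break
          rstar <- min(max(rstar - step, a), b)
        }
        if (is.finite(g_bnd(rstar, vc))) {
          note3(vc, rstar, bnd_rPd(rstar, vc),
                resid = c(R = NA_real_, P = NA_real_),
                at_limit = TRUE, kkt = kkt)
        }
      }
    }
    if (!is.null(best3)) cand[[length(cand) + 1]] <- best3
  }

  dGs <- vapply(cand, function(c) c$dG, numeric(1))
  scen_ids <- vapply(cand, function(c) c$scenario, integer(1))
  best <- cand[[which.min(dGs)]]
  labels <- c("disperse", "condensed", "both-coexist", "R-coexists",
              "P-coexists")
  dG_table <- stats::setNames(rep(NA_real_, 5), labels)
  for (k in seq_along(cand)) {
    s <- scen_ids[k]
    if (!is.finite(dG_table[s]) || dGs[k] < dG_table[s]) dG_table[s] <- dGs[k]
  }
  mu_of <- function(b) {
    c(R_d = if (b$rho_Rd > 0 && b$Vc < 1)
        chemical_potential(input, "R", "dilute", b$rho_Rd, b$rho_Pd)
      else NA_real_,
      P_d = if (b$rho_Pd > 0 && b$Vc < 1)
        chemical_potential(input, "P", "dilute", b$rho_Rd, b$rho_Pd)
      else NA_real_,
      R_c = if (b$rho_Rc > 0)
        chemical_potential(input, "R", "condensed", b$rho_Rc, b$rho_Pc)
      else NA_real_,
      P_c = if (b$rho_Pc > 0)
        chemical_potential(input, "P", "condensed", b$rho_Rc, b$rho_Pc)
      else NA_real_)
  }
  structure(list(
    scenario = best$scenario,
    scenario_label = labels[best$scenario],
    phase_separated = best$scenario %in% 3:5,
    rho_R_dilute = best$rho_Rd, rho_P_dilute = best$rho_Pd,
    rho_R_condensed = best$rho_Rc, rho_P_condensed = best$rho_Pc,
    c_R_dilute_mM = nm3_to_mM(best$rho_Rd),
    c_P_dilute_mM = nm3_to_mM(best$rho_Pd),
    c_R_condensed_mM = nm3_to_mM(best$rho_Rc),
    c_P_condensed_mM = nm3_to_mM(best$rho_Pc),
    Vc = best$Vc, dG = best$dG, dG_scenarios = dG_table,
    mu = mu_of(best), residuals = best$resid,
    at_packing_limit = isTRUE(best$at_limit),
    kkt_residual = best$kkt,
    packing = packing(best$rho_Rc, best$rho_Pc),
    input = input
  ), class = "theory_solution")
}

#' @export
#' @export
print.theory_solution <- function(x, ...) {
  cat(sprintf("<theory_solution> scenario %d (%s)%s, dG = %.4g kJ/mol/V\n",
              x$scenario, x$scenario_label,
              if (x$phase_separated) " [phase separated]" else "", x$dG))
  cat(sprintf("  dilute:    [R] = %.4g mM, [P] = %.4g mM\n",
              x$c_R_dilute_mM, x$c_P_dilute_mM))
  cat(sprintf("  condensed: [R] = %.4g mM, [P] = %.4g mM (Vc/V = %.3g)\n",
              x$c_R_condensed_mM, x$c_P_condensed_mM, x$Vc))
  invisible(x)
}

#' Update concentrations or temperature of a theory input
#'
#' Rebuilds a [theory_input()] with new total concentrations and/or
#' temperature while keeping the cached interaction integrals (which depend
#' only on charges, radii and kappa).
#'
#' @param input A [theory_input()].
#' @param c_R_mM,c_P_mM New total concentrations, mM (optional).
#' @param T_K New temperature, K (optional).
#' @return The updated `theory_input`.
#' @export
update_theory_input <- function(input, c_R_mM = NULL, c_P_mM = NULL,
                                T_K = NULL) {
  if (!is.null(c_R_mM)) {
    input$c_R_mM <- c_R_mM
    input$rho_R <- mM_to_nm3(c_R_mM)
  }
  if (!is.null(c_P_mM)) {
    input$c_P_mM <- c_P_mM
    input$rho_P <- mM_to_nm3(c_P_mM)
  }
  if (!is.null(T_K)) input$T_K <- T_K  # x integrals are T-independent
  input
}

#' Concentration-dependent phase map
#'
#' Solves the coexistence problem on a grid of total RNA and protein
#' concentrations. The interaction integrals are concentration-independent
#' and computed once.
#'
#' @param input A [theory_input()] (its concentrations are overridden).
#' @param c_R_grid_mM,c_P_grid_mM Concentration grids, mM (> 0).
#' @param ... Passed to [solve_coexistence()].
#' @return data.frame (long format): `c_R_mM`, `c_P_mM`, `scenario`, `ps`,
#'   dilute/condensed concentrations and `dG`.
#' @export
scan_concentration <- function(input, c_R_grid_mM, c_P_grid_mM, ...) {
  stopifnot(all(c_R_grid_mM > 0), all(c_P_grid_mM > 0))
  rows <- list()
  for (cR in c_R_grid_mM) for (cP in c_P_grid_mM) {
    sol <- solve_coexistence(update_theory_input(input, cR, cP), ...)
    rows[[length(rows) + 1]] <- data.frame(
      c_R_mM = cR, c_P_mM = cP, scenario = sol$scenario,
      ps = sol$phase_separated,
      c_R_dilute_mM = sol$c_R_dilute_mM, c_P_dilute_mM = sol$c_P_dilute_mM,
      c_R_condensed_mM = sol$c_R_condensed_mM,
      c_P_condensed_mM = sol$c_P_condensed_mM,
      Vc = sol$Vc, dG = sol$dG)
  }
  do.call(rbind, rows)
}

#' Charge-radius phase map at fixed concentrations
#'
#' Phase behaviour as a function of protein charge and radius at fixed
#' total concentrations (defaults 0.45 mM RNA / 0.35 mM protein, kappa =
#' 1.17, 298 K -- the standard binary-mixture scan conditions).
#'
#' @param q_P_grid,r_P_grid_nm Protein charge and radius grids.
#' @param c_R_mM,c_P_mM Total concentrations, mM.
#' @param gofr A [gofr_library()].
#' @param T_K,kappa See [theory_input()].
#' @param ... Passed to [solve_coexistence()].
#' @return data.frame: `q_P`, `r_P_nm`, `scenario`, `ps`, phase
#'   concentrations, `dG`.
#' @export
scan_charge_radius <- function(q_P_grid, r_P_grid_nm, c_R_mM = 0.45,
                               c_P_mM = 0.35, gofr = default_gofr_library(),
                               T_K = 298, kappa = 1.17, ...) {
  rows <- list()
  for (q in q_P_grid) for (r in r_P_grid_nm) {
    inp <- theory_input(q_P = q, r_P_nm = r, c_R_mM = c_R_mM,
                        c_P_mM = c_P_mM, T_K = T_K, kappa = kappa,
                        gofr = gofr)
    sol <- solve_coexistence(inp, ...)
    rows[[length(rows) + 1]] <- data.frame(
      q_P = q, r_P_nm = r, scenario = sol$scenario, ps = sol$phase_separated,
      c_R_dilute_mM = sol$c_R_dilute_mM, c_P_dilute_mM = sol$c_P_dilute_mM,
      c_R_condensed_mM = sol$c_R_condensed_mM,
      c_P_condensed_mM = sol$c_P_condensed_mM, dG = sol$dG)
  }
  do.call(rbind, rows)
}

#' Temperature scan (theoretical binodal)
#'
#' @param input A [theory_input()].
#' @param T_grid_K Temperatures, K (> 0).
#' @param ... Passed to [solve_coexistence()].
#' @return list with `per_T` (data.frame of PS flags and phase
#'   compositions) and `T_max_ps_K` (highest temperature with phase
#'   separation, or `NA`).
#' @export
scan_temperature <- function(input, T_grid_K, ...) {
  stopifnot(all(T_grid_K > 0))
  rows <- list()
  for (TT in sort(T_grid_K)) {
    sol <- solve_coexistence(update_theory_input(input, T_K = TT), ...)
    rows[[length(rows) + 1]] <- data.frame(
      T_K = TT, scenario = sol$scenario, ps = sol$phase_separated,
      c_R_dilute_mM = sol$c_R_dilute_mM,
      c_R_condensed_mM = sol$c_R_condensed_mM,
      c_P_condensed_mM = sol$c_P_condensed_mM,
      packing = sol$rho_R_condensed * input$V_R +
        sol$rho_P_condensed * input$V_P,
      Vc = sol$Vc, dG = sol$dG)
  }
  per_T <- do.call(rbind, rows)
  T_ps <- per_T$T_K[per_T$ps]
  list(per_T = per_T,
       T_max_ps_K = if (length(T_ps) > 0) max(T_ps) else NA_real_)
}
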