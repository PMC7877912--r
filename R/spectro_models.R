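# ---------------------------------------------------------------------------
# Forward models connecting phase-separation predictions to FRET
# efficiencies and DLS correlation functions.
# ---------------------------------------------------------------------------

#' Fraction of labeled RNA in the condensed phase
#'
#' Labeled (F) and unlabeled (U) RNA exchange between dilute and condensed
#' phases while the total RNA split `R_d`/`R_c` is maintained, with
#' partition equilibrium `K = [F_c][U_d] / ([F_d][U_c])` and conservation
#' `F = F_c + F_d`, `R_d = U_d + F_d`, `R_c = U_c + F_c`. Solving the
#' resulting quadratic for `[F_c]` (unique root in
#' `[max(0, F - R_d), min(F, R_c)]`) gives `f = F_c / F`. All
#' concentrations are with respect to the total volume; any common unit
#' works.
#'
#' @param R_d,R_c Total RNA in dilute / condensed phase.
#' @param F_total Labeled RNA concentration (`<= R_d + R_c`).
#' @param K Partition equilibrium constant (> 0; hydrophobic dye labels
#'   favour the condensate, K > 1; default 100).
#' @return Fraction `f` in `[0, 1]`, with attributes `F_c` and `F_d`.
#' @examples
#' fret_fraction_condensed(R_d = 0.1, R_c = 0.4, F_total = 0.008, K = 100)
#' @export
fret_fraction_condensed <- function(R_d, R_c, F_total, K = 100) {
  stopifnot(R_d >= 0, R_c >= 0, F_total >= 0, K > 0)
  if (F_total > R_d + R_c + 1e-12) {
    stop("F_total exceeds total RNA (labels are a subset of the RNA)")
  }
  if (F_total == 0) {
    f <- 0
    attr(f, "F_c") <- 0
    attr(f, "F_d") <- 0
    return(f)
  }
  if (R_c == 0) {
    f <- 0
    attr(f, "F_c") <- 0
    attr(f, "F_d") <- F_total
    return(f)
  }
  if (R_d == 0) {
    f <- 1
    attr(f, "F_c") <- F_total
    attr(f, "F_d") <- 0
    return(f)
  }
  # K = Fc (Rd - F + Fc) / ((F - Fc)(Rc - Fc))
  # -> (K - 1) Fc^2 - [K (Rc + F) + Rd - F] Fc + K F Rc = 0
  a <- K - 1
  b <- -(K * (R_c + F_total) + R_d - F_total)
  cc <- K * F_total * R_c
  lo <- max(0, F_total - R_d)
  hi <- min(F_total, R_c)
  if (abs(a) < 1e-12) {
    Fc <- -cc / b
  } else {
    disc <- sqrt(b^2 - 4 * a * cc)
    roots <- c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
    inside <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    if (length(inside) == 0) stop("no physical root for F_c")
    Fc <- inside[1]
  }
  Fc <- min(max(Fc, lo), hi)
  f <- Fc / F_total
  attr(f, "F_c") <- Fc
  attr(f, "F_d") <- F_total - Fc
  f
}

#' FRET efficiency from the condensed label fraction
#'
#' `E = E0 (1 - f) + Ec f`: a linear mix of the baseline efficiency at zero
#' protein (`E0`, transient dye-dye contacts only) and the condensed-phase
#' efficiency `Ec`.
#'
#' @param f Fraction of labeled RNA in the condensate, in `[0, 1]`.
#' @param E0 Baseline efficiency (default 0.24, the experimental background).
#' @param Ec Condensed-phase efficiency (from [fret_Ec()]).
#' @return Efficiency E.
#' @export
fret_efficiency <- function(f, E0 = 0.24, Ec) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  stopifnot(E0 >= 0, E0 <= 1, Ec >= 0, Ec <= 1)
  E0 * (1 - f) + Ec * f
}

#' Condensed-phase FRET efficiency from a distance distribution
#'
#' Convolves the distribution `P(r)` of minimum RNA-RNA distances in the
#' condensed phase with the Foerster kernel `1 / (1 + (r/r0)^6)`:
#' `Ec = Int P(r) / (1 + (r/r0)^6) dr` (trapezoid over the tabulated
#' distribution, which must integrate to 1 within 1e-6).
#'
#' @param P_r data.frame with columns `r_nm` and `p` (density per nm), or a
#'   two-column matrix.
#' @param r0_nm Transfer radius, nm (default 4.10 for the dye pair in the
#'   condensate environment).
#' @return Ec in `[0, 1]`.
#' @export
fret_Ec <- function(P_r, r0_nm = 4.10) {
  P_r <- as.data.frame(P_r)
  names(P_r)[1:2] <- c("r_nm", "p")
  r <- P_r$r_nm
  p <- P_r$p
  stopifnot(length(r) >= 2, all(diff(r) > 0), all(p >= 0))
  norm <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  if (abs(norm - 1) > 1e-6) {
    stop(sprintf("P(r) integrates to %.8f, not 1 (tolerance 1e-6)", norm))
  }
  kern <- 1 / (1 + (r / r0_nm)^6)
  f <- p * kern
  sum(diff(r) * (f[-1] + f[-length(f)]) / 2)
}

#' Distribution of minimum same-species distances in a trajectory
#'
#' For every selected particle and frame, the minimum-image distance to its
#' nearest selected neighbour; returned as a normalized density on a
#' distance grid. Restricted to cluster members when `members` is given
#' (the condensed-phase minimum RNA-RNA distance distribution that enters
#' [fret_Ec()]).
#'
#' @param traj A `cg_trajectory`.
#' @param species Species name(s).
#' @param frames Frame indices (default all).
#' @param members Optional integer vector: restrict to these particle
#'   indices.
#' @param bin_nm Histogram bin width, nm.
#' @return data.frame with columns `r_nm` (bin centres) and `p`
#'   (density, integrates to 1).
#' @export
min_distance_distribution <- function(traj, species, frames = NULL,
                                      members = NULL, bin_nm = 0.1) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  sel <- which(traj$species_names[traj$species_index] %in% species)
  if (!is.null(members)) sel <- intersect(sel, members)
  if (length(sel) < 2) stop("need >= 2 selected particles")
  box <- traj$box_nm
  mins <- numeric(0)
  for (f in frames) {
    fr <- get_frame(traj, f)[sel, , drop = FALSE]
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(fr[, k], fr[, k], "-")
      dk <- dk - box * round(dk / box)
      d2 <- d2 + dk^2
    }
    diag(d2) <- Inf
    mins <- c(mins, sqrt(apply(d2, 1, min)))
  }
  h <- graphics::hist(mins, breaks = seq(0, max(mins) + bin_nm, by = bin_nm),
                      plot = FALSE)
  data.frame(r_nm = h$mids, p = h$density)
}

#' DLS instrument constants
#'
#' Defaults match a standard backscatter instrument: solvent refractive
#' index 1.335, laser wavelength 633 nm, scattering angle 173 degrees,
#' 298 K, solvent viscosity 0.8882 cP.
#'
#' @param n Refractive index.
#' @param lambda_nm Laser wavelength, nm.
#' @param theta_deg Scattering angle, degrees (0, 180].
#' @param T_K Temperature, K.
#' @param eta_cP Viscosity, cP.
#' @return Object of class `"dls_instrument"` with the scattering wave
#'   vector `q_per_nm` precomputed.
#' @export
dls_instrument <- function(n = 1.335, lambda_nm = 633, theta_deg = 173,
                           T_K = 298, eta_cP = 0.8882) {
  stopifnot(n > 0, lambda_nm > 0, theta_deg > 0, theta_deg <= 180,
            T_K > 0, eta_cP > 0)
  q <- 4 * pi * n / lambda_nm * sin(theta_deg * pi / 360)
  structure(list(n = n, lambda_nm = lambda_nm, theta_deg = theta_deg,
                 T_K = T_K, eta_cP = eta_cP, q_per_nm = q),
            class = "dls_instrument")
}

#' Stokes-Einstein diffusion coefficient for a particle diameter
#'
#' `D = kB T / (3 pi eta d)` in nm^2/s for a diameter in nm (the
#' hydrodynamic friction of a sphere of diameter `d = 2r` is
#' `6 pi eta r = 3 pi eta d`).
#'
#' @param d_nm Particle diameter(s), nm.
#' @param instrument A [dls_instrument()].
#' @return D in nm^2/s.
#' @export
dls_diffusion <- function(d_nm, instrument = dls_instrument()) {
  stopifnot(all(d_nm > 0))
  kB_J <- 1.380649e-23
  eta <- instrument$eta_cP * 1e-3  # Pa s
  D_m2s <- kB_J * instrument$T_K / (3 * pi * eta * d_nm * 1e-9)
  D_m2s * 1e18
}

#' DLS fit parameter set
#'
#' The polydisperse fit model: a ladder of `n_ladder` (default 10) cluster
#' sizes starting at the smallest particle diameter `d_c` with amplitudes
#' decaying as `a_c exp(-i / t_c)`, plus up to `n_discrete` (default cap 4)
#' discrete sizes `d_i` with amplitudes `a_i`. The i-mer diameter follows
#' `size_of(i) = i^nu * d_c` with `nu = 1` (linear, default) or `1/3`
#' (volumetric growth).
#'
#' @param d_c Smallest cluster diameter, nm (> 0).
#' @param a_c Cluster amplitude (>= 0).
#' @param t_c Ladder decay constant (> 0).
#' @param d_i Discrete diameters, nm (length <= `max_discrete`).
#' @param a_i Discrete amplitudes (same length as `d_i`).
#' @param nu Ladder size exponent (1 or 1/3).
#' @param n_ladder Ladder length (default 10).
#' @param max_discrete Cap on discrete sizes (default 4).
#' @return Object of class `"dls_fit_params"`.
#' @export
dls_fit_params <- function(d_c, a_c, t_c, d_i = numeric(0),
                           a_i = numeric(0), nu = 1, n_ladder = 10L,
                           max_discrete = 4L) {
  stopifnot(d_c > 0, a_c >= 0, t_c > 0, length(d_i) == length(a_i),
            length(d_i) <= max_discrete, all(d_i > 0), all(a_i >= 0),
            nu %in% c(1, 1 / 3))
  structure(list(d_c = d_c, a_c = a_c, t_c = t_c, d_i = d_i, a_i = a_i,
                 nu = nu, n_ladder = as.integer(n_ladder)),
            class = "dls_fit_params")
}

#' @export
print.dls_fit_params <- function(x, ...) {
  cat(sprintf("<dls_fit_params> ladder: d_c = %.2f nm, a_c = %.3f, t_c = %.3g (x%d, nu = %.3g)\n",
              x$d_c, x$a_c, x$t_c, x$n_ladder, x$nu))
  if (length(x$d_i) > 0) {
    cat(sprintf("  discrete: %s\n", paste(sprintf("%.4g nm (a = %.3f)",
                                                  x$d_i, x$a_i), collapse = ", ")))
  }
  if (!is.null(attr(x, "chi2"))) cat(sprintf("  chi2 = %.4g\n", attr(x, "chi2")))
  invisible(x)
}

#' Model intensity correlation function g2(tau) - 1
#'
#' `g2(tau) - 1 = sum_{i=1..n_ladder} a_c^2 exp(-2 i / t_c) G(tau; i^nu d_c)
#'              + sum_j a_j^2 G(tau; d_j)`
#' with `G(tau; d) = exp(-2 q^2 D(d) tau)` (the squared field correlation of
#' a monodisperse species via the Siegert relation) and Stokes-Einstein
#' `D(d)`.
#'
#' @param tau_s Lag times, s (> 0 or 0).
#' @param fit A [dls_fit_params()].
#' @param instrument A [dls_instrument()].
#' @return Numeric vector `g2 - 1` on the tau grid.
#' @export
dls_g2_model <- function(tau_s, fit, instrument = dls_instrument()) {
  stopifnot(all(tau_s >= 0))
  q2 <- instrument$q_per_nm^2
  out <- numeric(length(tau_s))
  for (i in seq_len(fit$n_ladder)) {
    d <- i^fit$nu * fit$d_c
    D <- dls_diffusion(d, instrument)
    out <- out + fit$a_c^2 * exp(-2 * i / fit$t_c) * exp(-2 * q2 * D * tau_s)
  }
  for (j in seq_along(fit$d_i)) {
    D <- dls_diffusion(fit$d_i[j], instrument)
    out <- out + fit$a_i[j]^2 * exp(-2 * q2 * D * tau_s)
  }
  out
}

#' Fit the multi-exponential DLS model to a correlation function
#'
#' Seeded multi-start bounded nonlinear least squares
#' (Levenberg-Marquardt) of [dls_g2_model()] against measured
#' `g2(tau) - 1` data. Reported `chi2` is the sum of squared residuals
#' divided by the number of points (normalization conventions differ
#' between instruments, so it is not comparable across sources).
#'
#' @param tau_s Lag times, s (>= 20 points).
#' @param g2m1 Measured `g2 - 1` values.
#' @param n_discrete Number of discrete sizes to fit (0..4).
#' @param instrument A [dls_instrument()].
#' @param seed RNG seed for the multi-start initialization.
#' @param n_starts Number of random starts.
#' @param include_ladder Fit the cluster ladder (set `FALSE` to force
#'   `a_c = 0`, e.g. for simple mixtures).
#' @param nu Ladder size exponent.
#' @return A [dls_fit_params()] with attributes `chi2` (per-point),
#'   `converged`, and `residuals`.
#' @export
dls_fit <- function(tau_s, g2m1, n_discrete = 2L,
                    instrument = dls_instrument(), seed = 1L,
                    n_starts = 20L, include_ladder = TRUE, nu = 1) {
  stopifnot(length(tau_s) >= 20, length(tau_s) == length(g2m1),
            n_discrete >= 0, n_discrete <= 4)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  # parameters (log scale for sizes/times): [log d_c, a_c, log t_c,
  #  log d_1.., a_1..]
  span_d <- c(1, 1e5)     # nm, diameters
  mk_fit <- function(p) {
    if (include_ladder) {
      d_c <- exp(p[1]); a_c <- p[2]; t_c <- exp(p[3]); rest <- p[-(1:3)]
    } else {
      d_c <- 1; a_c <- 0; t_c <- 1; rest <- p
    }
    d_i <- a_i <- numeric(0)
    if (n_discrete > 0) {
      d_i <- exp(rest[seq_len(n_discrete)])
      a_i <- rest[n_discrete + seq_len(n_discrete)]
    }
    dls_fit_params(d_c = max(d_c, 1e-3), a_c = abs(a_c), t_c = max(t_c, 1e-3),
                   d_i = d_i, a_i = abs(a_i), nu = nu)
  }
  resid_fn <- function(p) dls_g2_model(tau_s, mk_fit(p), instrument) - g2m1
  n_par <- (if (include_ladder) 3L else 0L) + 2L * n_discrete
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- numeric(0)
    if (include_ladder) {
      p0 <- c(log(stats::runif(1, 2, 50)), stats::runif(1, 0.05, 0.5),
              log(stats::runif(1, 1, 50)))
    }
    if (n_discrete > 0) {
      p0 <- c(p0,
              sort(stats::runif(n_discrete, log(span_d[1]), log(span_d[2]))),
              stats::runif(n_discrete, 0.1, 1))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("DLS fit failed from every start")
  out <- mk_fit(best$fit$par)
  # order discrete sizes ascending for reporting
  if (length(out$d_i) > 1) {
    o <- order(out$d_i)
    out$d_i <- out$d_i[o]
    out$a_i <- out$a_i[o]
  }
  attr(out, "chi2") <- best$ss / length(tau_s)
  attr(out, "converged") <- best$fit$info %in% 1:4
  attr(out, "residuals") <- best$fit$fvec
  if (!attr(out, "converged")) {
    warning("DLS fit did not formally converge; returning best found")
  }
  out
}

#' FRET predictions along a protein concentration series
#'
#' End-to-end forward model: for each protein concentration, solve the
#' coacervation theory, convert the dilute/condensed RNA densities to
#' total-volume concentrations `[R_d] = rho_Rd (V - V_c)/V` and
#' `[R_c] = rho_Rc V_c/V`, partition the labeled RNA with equilibrium
#' constant `K`, and mix the baseline and condensed-phase efficiencies.
#'
#' @param input A [theory_input()] (RNA concentration fixed; protein
#'   concentration overridden per grid point).
#' @param c_P_grid_mM Protein concentrations, mM.
#' @param F_total_mM Labeled RNA concentration, mM.
#' @param E0,Ec Baseline and condensed-phase FRET efficiencies.
#' @param K Label partition constant.
#' @param ... Passed to [solve_coexistence()].
#' @return data.frame: `c_P_mM`, `R_d_mM`, `R_c_mM`, `f`, `E`.
#' @export
fret_predict_series <- function(input, c_P_grid_mM, F_total_mM = 0.05,
                                E0 = 0.24, Ec = 0.7, K = 100, ...) {
  rows <- list()
  for (cP in c_P_grid_mM) {
    sol <- solve_coexistence(update_theory_input(input, c_P_mM = cP), ...)
    R_d <- sol$c_R_dilute_mM * (1 - sol$Vc)
    R_c <- sol$c_R_condensed_mM * sol$Vc
    f <- fret_fraction_condensed(R_d, R_c, min(F_total_mM, R_d + R_c), K)
    rows[[length(rows) + 1]] <- data.frame(
      c_P_mM = cP, R_d_mM = R_d, R_c_mM = R_c, f = as.numeric(f),
      E = fret_efficiency(as.numeric(f), E0, Ec))
  }
  do.call(rbind, rows)
}
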