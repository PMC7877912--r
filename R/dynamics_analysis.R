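# Unwrap a wrapped periodic trajectory by accumulating minimum-image
# displacements between consecutive frames. Valid only if no particle moves
# more than box/4 between saved frames; violations raise an error.
unwrap_trajectory <- function(traj) {
  fr <- traj$frames
  box <- traj$box_nm
  nf <- dim(fr)[3]
  out <- fr
  if (nf < 2) return(out)
  for (f in 2:nf) {
    d <- fr[, , f] - fr[, , f - 1]
    d <- d - box * round(d / box)
    if (max(abs(d)) > box / 4) {
      stop(sprintf(
        "per-interval displacement %.2f nm exceeds box/4 = %.2f nm between frames %d and %d; save more frequently",
        max(abs(d)), box / 4, f - 1, f))
    }
    out[, , f] <- out[, , f - 1] + d
  }
  out
}

#' Mean-squared displacement of selected particles
#'
#' Time- and particle-averaged MSD over a grid of lag times, computed on
#' the unwrapped trajectory (periodic crossings are tracked by per-interval
#' minimum-image accumulation). With a membership filter, only
#' `(t, t + tau)` windows during which the particle stayed inside (or
#' outside) the condensate for the entire lag contribute; membership is a
#' logical particles x frames matrix (e.g. built from cluster membership
#' per frame).
#'
#' @param traj A `cg_trajectory`.
#' @param selection Integer particle indices or species name(s); default all.
#' @param lags_ns Lag-time grid, ns (defaults to all multiples of the frame
#'   spacing up to a third of the span).
#' @param membership Optional logical particles x frames matrix; a window
#'   counts only if all frames in it are `TRUE` for that particle.
#' @return An object of class `"msd_result"`: data.frame-backed list with
#'   `tau_ns`, `msd_nm2`, `n_windows`, plus the selection description.
#' @export
msd <- function(traj, selection = NULL, lags_ns = NULL, membership = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames")
  times <- traj$times_ns
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("frames must be evenly spaced")
  dt <- dt[1]
  if (is.character(selection)) {
    selection <- which(traj$species_names[traj$species_index] %in% selection)
  }
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[1])
  if (length(selection) == 0) stop("empty selection")
  un <- unwrap_trajectory(traj)
  if (is.null(lags_ns)) {
    max_lag <- max(1L, floor((nf - 1) / 3))
    lags <- seq_len(max_lag)
  } else {
    lags <- round(lags_ns / dt)
    if (any(lags < 1) || any(lags > nf - 1)) stop("lag beyond trajectory span")
  }
  msd_v <- numeric(length(lags))
  nw <- numeric(length(lags))
  for (li in seq_along(lags)) {
    L <- lags[li]
    acc <- 0
    cnt <- 0
    for (t0 in seq_len(nf - L)) {
      d <- un[selection, , t0 + L, drop = FALSE] - un[selection, , t0, drop = FALSE]
      sq <- rowSums(matrix(d, ncol = 3)^2)
      if (!is.null(membership)) {
        ok <- apply(membership[selection, t0:(t0 + L), drop = FALSE], 1, all)
        sq <- sq[ok]
      }
      acc <- acc + sum(sq)
      cnt <- cnt + length(sq)
    }
    msd_v[li] <- if (cnt > 0) acc / cnt else NA_real_
    nw[li] <- cnt
  }
  structure(list(
    tau_ns = lags * dt, msd_nm2 = msd_v, n_windows = nw,
    selection = selection,
    filter = if (is.null(membership)) "none" else "condensate membership"
  ), class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d lags (%.3g - %.3g ns), %d particles, filter: %s\n",
              length(x$tau_ns), min(x$tau_ns), max(x$tau_ns),
              length(x$selection), x$filter))
  invisible(x)
}

#' Translational diffusion coefficient from an MSD curve
#'
#' Fits `MSD(tau) = 6 D tau` (a least-squares line through the origin) over
#' lags up to `tau_max_ns` and returns `D = slope / 6`. Protocol presets:
#' 20 ns (cytoplasm-style analysis of finely saved segments) and 2000 ns
#' (= 2 us, five-component-style analysis of coarsely saved long runs).
#' An intercept mode is available for diagnostics.
#'
#' @param m An [msd()] result.
#' @param tau_max_ns Upper lag bound for the fit, ns.
#' @param intercept Fit an intercept (diagnostic mode; `D` still from the
#'   slope).
#' @return `D_tr` in nm^2/us, with attributes `slope_nm2_per_ns`,
#'   `intercept_nm2` and `n_points`. Note 1 nm^2/ns = 1000 nm^2/us.
#' @export
fit_diffusion <- function(m, tau_max_ns = 20, intercept = FALSE) {
  keep <- which(m$tau_ns <= tau_max_ns & is.finite(m$msd_nm2))
  if (length(keep) < 3) stop("need >= 3 lag points within tau_max_ns")
  x <- m$tau_ns[keep]
  y <- m$msd_nm2[keep]
  if (intercept) {
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- unname(fit$coefficients[2])
    icpt <- unname(fit$coefficients[1])
  } else {
    slope <- sum(x * y) / sum(x^2)
    icpt <- 0
  }
  if (!is.finite(slope)) stop("degenerate MSD fit")
  D <- slope / 6 * 1000  # nm^2/ns -> nm^2/us
  attr(D, "slope_nm2_per_ns") <- slope
  attr(D, "intercept_nm2") <- icpt
  attr(D, "n_points") <- length(keep)
  D
}
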