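# minimum-image pairwise distance matrix for one frame (cubic box)
min_image_dist <- function(frame, box_nm) {
  n <- nrow(frame)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(frame[, k], frame[, k], "-")
    dk <- dk - box_nm * round(dk / box_nm)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Contact criterion for condensate detection
#'
#' Two particles are in contact when their minimum-image centre distance is
#' strictly less than `sigma_ij + delta_nm`. `delta_nm = 0.7` captures
#' direct molecular interactions (transient clusters); `delta_nm = 2.2`
#' includes all contacts within the first peak of the pair correlation
#' function and is the condensate criterion. `pair_classes` restricts which
#' species pairs define edges (e.g. only RNA-protein contacts so RNA and
#' ribosome clusters can be analyzed separately in one system); `NULL`
#' means all pairs count.
#'
#' @param delta_nm Contact distance margin added to `sigma_ij`, nm (>= 0).
#' @param pair_classes `NULL` (all pairs), or a list of `list(A = <species
#'   names>, B = <species names>)` entries; an edge is allowed if one
#'   particle's species is in `A` and the other's in `B` (or vice versa).
#' @return An object of class `"contact_criterion"`.
#' @export
contact_criterion <- function(delta_nm = 2.2, pair_classes = NULL) {
  stopifnot(delta_nm >= 0)
  if (!is.null(pair_classes)) {
    stopifnot(is.list(pair_classes), length(pair_classes) >= 1)
    for (pc in pair_classes) {
      if (is.null(pc$A) || is.null(pc$B) || length(pc$A) == 0 || length(pc$B) == 0)
        stop("each pair class needs non-empty A and B species sets")
    }
  }
  structure(list(delta_nm = delta_nm, pair_classes = pair_classes),
            class = "contact_criterion")
}

#' Contact graph of one frame
#'
#' Edge `(i, j)` iff the species pair is allowed by the criterion's pair
#' classes and the minimum-image distance is strictly below
#' `sigma_ij + delta_nm`.
#'
#' @param frame N x 3 coordinates, nm.
#' @param spec A [system_spec()].
#' @param criterion A [contact_criterion()].
#' @return Two-column integer matrix of edges (i < j); zero rows if none.
#' @export
contact_graph <- function(frame, spec, criterion = contact_criterion()) {
  idx <- spec_species_index(spec)
  if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  stopifnot(nrow(frame) == length(idx))
  tabs <- spec_pair_tables(spec)
  names_sp <- vapply(spec$species, function(s) s$name, character(1))
  d <- min_image_dist(frame, spec$box_nm)
  thr <- tabs$sigma_ij[idx, idx, drop = FALSE] + criterion$delta_nm
  adj <- d < thr
  diag(adj) <- FALSE
  if (!is.null(criterion$pair_classes)) {
    allowed <- matrix(FALSE, length(names_sp), length(names_sp))
    for (pc in criterion$pair_classes) {
      ia <- which(names_sp %in% pc$A)
      ib <- which(names_sp %in% pc$B)
      allowed[ia, ib] <- TRUE
      allowed[ib, ia] <- TRUE
    }
    adj <- adj & allowed[idx, idx, drop = FALSE]
  }
  which_edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  colnames(which_edges) <- c("i", "j")
  which_edges[order(which_edges[, 1], which_edges[, 2]), , drop = FALSE]
}

#' Connected components of a contact graph
#'
#' All particles in one connected graph belong to one cluster; the clusters
#' partition the participant set.
#'
#' @param edges Two-column integer edge matrix (from [contact_graph()]).
#' @param participants Integer vector of particle indices to partition
#'   (isolated participants become singleton clusters).
#' @return An object of class `"cluster_set"`: list with `clusters` (list of
#'   integer vectors, sorted by decreasing size), `sizes`, and
#'   `membership` (named by participant index).
#' @export
connected_clusters <- function(edges, participants) {
  participants <- sort(unique(as.integer(participants)))
  g <- igraph::make_empty_graph(n = length(participants), directed = FALSE)
  if (nrow(edges) > 0) {
    keep <- edges[, 1] %in% participants & edges[, 2] %in% participants
    e <- edges[keep, , drop = FALSE]
    map <- match(as.vector(t(e)), participants)
    g <- igraph::add_edges(g, map)
  }
  comp <- igraph::components(g)
  clusters <- split(participants, comp$membership)
  clusters <- clusters[order(vapply(clusters, length, integer(1)),
                             decreasing = TRUE)]
  names(clusters) <- NULL
  structure(list(
    clusters = clusters,
    sizes = vapply(clusters, length, integer(1)),
    membership = stats::setNames(comp$membership, participants)
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d particles; sizes: %s\n",
              length(x$clusters), sum(x$sizes),
              paste(utils::head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

# unwrap a set of positions around a reference using minimum image
unwrap_around <- function(coords, box_nm) {
  ref <- coords[1, ]
  d <- sweep(coords, 2, ref)
  d <- d - box_nm * round(d / box_nm)
  sweep(d, 2, ref, "+")
}

#' Condensate volume of a cluster (Monte-Carlo union of spheres)
#'
#' The condensate volume is the volume of the union of spheres of radius
#' `r_i + probe_nm` centred on the cluster members (probe 2.2 nm,
#' consistent with the condensate contact criterion). Estimated by seeded
#' Monte-Carlo sampling over the cluster bounding box until the relative
#' standard error falls below `rel_se` (or `max_samples` is hit). Cluster
#' members are unwrapped around the first member before sampling, so the
#' cluster must not span more than half the box.
#'
#' @param frame N x 3 coordinates, nm.
#' @param cluster Integer vector of member particle indices (non-empty).
#' @param spec A [system_spec()].
#' @param probe_nm Probe radius added to each particle radius, nm.
#' @param rel_se Target relative standard error (default 0.01).
#' @param max_samples Sampling budget.
#' @param seed RNG seed.
#' @return Volume in nm^3, with attribute `"rel_se"`.
#' @export
condensate_volume <- function(frame, cluster, spec, probe_nm = 2.2,
                              rel_se = 0.01, max_samples = 400000L,
                              seed = 1L) {
  stopifnot(length(cluster) >= 1)
  if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  idx <- spec_species_index(spec)
  radii_all <- vapply(spec$species, function(s) s$radius_nm, numeric(1))
  rs <- radii_all[idx[cluster]] + probe_nm
  xyz <- unwrap_around(frame[cluster, , drop = FALSE], spec$box_nm)
  lo <- apply(xyz - rs, 2, min)
  hi <- apply(xyz + rs, 2, max)
  vbb <- prod(hi - lo)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  hit <- 0L
  tot <- 0L
  batch <- 20000L
  repeat {
    pts <- cbind(stats::runif(batch, lo[1], hi[1]),
                 stats::runif(batch, lo[2], hi[2]),
                 stats::runif(batch, lo[3], hi[3]))
    inside <- rep(FALSE, batch)
    for (m in seq_along(rs)) {
      notin <- which(!inside)
      if (length(notin) == 0) break
      dm <- sweep(pts[notin, , drop = FALSE], 2, xyz[m, ])
      inside[notin] <- rowSums(dm^2) <= rs[m]^2
    }
    hit <- hit + sum(inside)
    tot <- tot + batch
    p <- hit / tot
    if (p > 0) {
      rse <- sqrt((1 - p) / (p * tot))
      if (rse < rel_se || tot >= max_samples) break
    } else if (tot >= max_samples) break
  }
  v <- vbb * hit / tot
  attr(v, "rel_se") <- if (hit > 0) sqrt((1 - hit / tot) / hit) else NA_real_
  v
}

#' Condensate volume by voxel-grid counting (cross-check)
#'
#' Deterministic alternative to [condensate_volume()]: counts voxels of
#' edge `voxel_nm` whose centre lies inside the sphere union.
#'
#' @inheritParams condensate_volume
#' @param voxel_nm Voxel edge length, nm (default 0.25).
#' @return Volume in nm^3.
#' @export
condensate_volume_voxel <- function(frame, cluster, spec, probe_nm = 2.2,
                                    voxel_nm = 0.25) {
  stopifnot(length(cluster) >= 1)
  if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  idx <- spec_species_index(spec)
  radii_all <- vapply(spec$species, function(s) s$radius_nm, numeric(1))
  rs <- radii_all[idx[cluster]] + probe_nm
  xyz <- unwrap_around(frame[cluster, , drop = FALSE], spec$box_nm)
  lo <- apply(xyz - rs, 2, min)
  hi <- apply(xyz + rs, 2, max)
  gx <- seq(lo[1] + voxel_nm / 2, hi[1], by = voxel_nm)
  gy <- seq(lo[2] + voxel_nm / 2, hi[2], by = voxel_nm)
  gz <- seq(lo[3] + voxel_nm / 2, hi[3], by = voxel_nm)
  count <- 0
  # slab-wise to bound memory
  for (z in gz) {
    pts <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)), z)
    inside <- rep(FALSE, nrow(pts))
    for (m in seq_along(rs)) {
      notin <- which(!inside)
      if (length(notin) == 0) break
      dm <- sweep(pts[notin, , drop = FALSE], 2, xyz[m, ])
      inside[notin] <- rowSums(dm^2) <= rs[m]^2
    }
    count <- count + sum(inside)
  }
  count * voxel_nm^3
}

#' Radial distribution function from a trajectory
#'
#' Standard periodic-box pair correlation between two species selections,
#' normalized so uncorrelated particles give g(r) = 1 at large r.
#'
#' @param traj A `cg_trajectory`.
#' @param speciesA,speciesB Species names (may be equal).
#' @param bin_nm Bin width, nm (must be <= box/4).
#' @param r_max_nm Upper distance, nm (default box/2).
#' @param frames Frame indices to average over (default all).
#' @return data.frame with columns `r_nm` (bin centres) and `g`.
#' @export
rdf <- function(traj, speciesA, speciesB, bin_nm = 0.1, r_max_nm = NULL,
                frames = NULL) {
  box <- traj$box_nm
  if (bin_nm > box / 4) stop("bin_nm larger than box/4")
  if (is.null(r_max_nm)) r_max_nm <- box / 2
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  ia <- which(traj$species_names[traj$species_index] %in% speciesA)
  ib <- which(traj$species_names[traj$species_index] %in% speciesB)
  if (length(ia) == 0 || length(ib) == 0) stop("empty species selection")
  same <- setequal(ia, ib)
  breaks <- seq(0, r_max_nm, by = bin_nm)
  counts <- numeric(length(breaks) - 1)
  for (f in frames) {
    fr <- get_frame(traj, f)
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(fr[ia, k], fr[ib, k], "-")
      dk <- dk - box * round(dk / box)
      d2 <- d2 + dk^2
    }
    d <- sqrt(d2)
    if (same) d <- d[upper.tri(d)]
    d <- d[d > 0 & d < r_max_nm]
    counts <- counts + graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  }
  vshell <- (4 / 3) * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  npairs <- if (same) length(ia) * (length(ia) - 1) / 2 else length(ia) * length(ib)
  ideal <- npairs * vshell / box^3
  data.frame(r_nm = (breaks[-1] + breaks[-length(breaks)]) / 2,
             g = counts / (length(frames) * ideal))
}

#' Per-frame phase volume fractions and phase-separation flag
#'
#' Condensates are clusters with at least `min_cluster_size` members under
#' the contact criterion. Per frame, the condensed-phase volume is the sum
#' of [condensate_volume()] over condensates; the dilute volume is the box
#' volume minus all condensate volumes. `phi_H` is the molecular volume of
#' the selected species inside condensates divided by the condensed volume,
#' `phi_L` the analogue outside. The phase-separation flag requires at
#' least half of the species particles in clusters of size >=
#' `min_cluster_size` on average over the analyzed frames.
#'
#' @param traj A `cg_trajectory`.
#' @param species Species name(s) whose partitioning is measured.
#' @param criterion A [contact_criterion()].
#' @param min_cluster_size Condensate size threshold (default 10).
#' @param probe_nm Probe radius for condensate volumes, nm.
#' @param frames Frame indices to analyze (default all).
#' @param seed Seed for the Monte-Carlo volume estimates.
#' @return An object of class `"phase_fractions"`: list with `per_frame`
#'   (data.frame: frame, time_ns, n_in, n_out, phi_H, phi_L,
#'   fraction_in_large, v_condensed_nm3), `ps_flag`, `mean_fraction_in_large`,
#'   and `species`.
#' @export
phase_fractions <- function(traj, species, criterion = contact_criterion(),
                            min_cluster_size = 10L, probe_nm = 2.2,
                            frames = NULL, seed = 1L) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  spec <- traj$spec
  idx <- traj$species_index
  names_sp <- traj$species_names
  sel <- which(names_sp[idx] %in% species)
  if (length(sel) == 0) stop("empty species selection")
  radii_all <- vapply(spec$species, function(s) s$radius_nm, numeric(1))
  vpart <- (4 / 3) * pi * radii_all^3
  vbox <- traj$box_nm^3
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    fr <- get_frame(traj, f)
    edges <- contact_graph(fr, spec, criterion)
    cs <- connected_clusters(edges, seq_along(idx))
    big <- cs$clusters[cs$sizes >= min_cluster_size]
    if (length(big) > 0) {
      vcond <- sum(vapply(seq_along(big), function(b)
        as.numeric(condensate_volume(fr, big[[b]], spec, probe_nm,
                                     seed = seed + 1000L * f + b)),
        numeric(1)))
      members <- unlist(big)
    } else {
      vcond <- 0
      members <- integer(0)
    }
    in_sel <- intersect(members, sel)
    out_sel <- setdiff(sel, members)
    vdil <- max(vbox - vcond, 0)
    phi_H <- if (vcond > 0) sum(vpart[idx[in_sel]]) / vcond else NA_real_
    phi_L <- if (vdil > 0) sum(vpart[idx[out_sel]]) / vdil else NA_real_
    rows[[k]] <- data.frame(
      frame = f, time_ns = traj$times_ns[f],
      n_in = length(in_sel), n_out = length(out_sel),
      phi_H = phi_H, phi_L = phi_L,
      fraction_in_large = length(in_sel) / length(sel),
      v_condensed_nm3 = vcond)
  }
  per_frame <- do.call(rbind, rows)
  mean_frac <- mean(per_frame$fraction_in_large)
  structure(list(
    per_frame = per_frame,
    ps_flag = mean_frac >= 0.5,
    mean_fraction_in_large = mean_frac,
    species = species,
    min_cluster_size = min_cluster_size
  ), class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf("<phase_fractions> species %s: PS = %s (fraction in clusters >= %d: %.2f)\n",
              paste(x$species, collapse = "+"),
              x$ps_flag, x$min_cluster_size, x$mean_fraction_in_large))
  cat(sprintf("  mean phi_H = %.4g, mean phi_L = %.4g over %d frames\n",
              mean(x$per_frame$phi_H, na.rm = TRUE),
              mean(x$per_frame$phi_L, na.rm = TRUE), nrow(x$per_frame)))
  invisible(x)
}

#' Fit the critical point from coexisting volume fractions
#'
#' Fits the coexistence data {T, phi_H, phi_L} to the order-parameter and
#' diameter relations
#' `phi_H - phi_L = A (Tc - T)^0.32` and
#' `(phi_H + phi_L)/2 = phi_c + B (T - Tc)`,
#' with the 3D Ising exponent 0.32 held fixed. For a trial `Tc` both
#' relations are linear least-squares problems; `Tc` is profiled by
#' minimizing the total squared residual.
#'
#' @param df data.frame with columns `T_K`, `phi_H`, `phi_L` (>= 4
#'   temperatures with `phi_H > phi_L`).
#' @param Tc_range Search interval for `Tc` (default just above the data
#'   up to 3x the span).
#' @return An object of class `"critical_fit"`: list with `Tc_K`, `phi_c`,
#'   `amplitude_A`, `slope_B`, `residual_ss`, and `fitted` (data.frame).
#' @export
fit_critical_point <- function(df, Tc_range = NULL) {
  stopifnot(all(c("T_K", "phi_H", "phi_L") %in% names(df)))
  df <- df[df$phi_H > df$phi_L, , drop = FALSE]
  if (nrow(df) < 4) stop("need >= 4 temperatures with phi_H > phi_L")
  Tmax <- max(df$T_K)
  if (is.null(Tc_range)) Tc_range <- c(Tmax + 1e-6, Tmax + 3 * diff(range(df$T_K)) + 10)
  ssr <- function(Tc) {
    xo <- (Tc - df$T_K)^0.32
    A <- sum(xo * (df$phi_H - df$phi_L)) / sum(xo^2)
    mid <- (df$phi_H + df$phi_L) / 2
    fit2 <- stats::lm.fit(cbind(1, df$T_K - Tc), mid)
    sum((df$phi_H - df$phi_L - A * xo)^2) + sum(fit2$residuals^2)
  }
  opt <- stats::optimize(ssr, Tc_range)
  Tc <- opt$minimum
  xo <- (Tc - df$T_K)^0.32
  A <- sum(xo * (df$phi_H - df$phi_L)) / sum(xo^2)
  mid <- (df$phi_H + df$phi_L) / 2
  fit2 <- stats::lm.fit(cbind(1, df$T_K - Tc), mid)
  phi_c <- unname(fit2$coefficients[1])
  B <- unname(fit2$coefficients[2])
  fitted <- data.frame(
    T_K = df$T_K,
    dphi_fit = A * xo,
    mid_fit = phi_c + B * (df$T_K - Tc))
  structure(list(
    Tc_K = Tc, phi_c = phi_c, amplitude_A = A, slope_B = B,
    residual_ss = opt$objective, fitted = fitted, data = df
  ), class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("<critical_fit> Tc = %.1f K, phi_c = %.4g, A = %.4g, B = %.3g (SSR %.3g)\n",
              x$Tc_K, x$phi_c, x$amplitude_A, x$slope_B, x$residual_ss))
  invisible(x)
}
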