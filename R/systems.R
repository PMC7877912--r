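#' Built-in binary-mixture species table
#'
#' Radii (volume-equivalent sphere radii, nm) and nominal net charges (e) for
#' the globular proteins used in the binary RNA-protein mixtures, plus the
#' 47-nt J345 Varkud satellite ribozyme RNA.
#'
#' @return A data.frame with columns `name`, `charge_e`, `radius_nm`.
#' @export
binary_species_table <- function() {
  data.frame(
    name = c("RNA", "myoglobin", "trypsin", "lysozyme", "cytochromeC",
             "LDH", "ADH", "BSA"),
    charge_e = c(-46, 2, 6, 8, 11, 4, 8, -17),
    radius_nm = c(1.47, 1.64, 1.81, 1.54, 1.45, 2.68, 2.79, 2.58),
    stringsAsFactors = FALSE
  )
}

#' Particle count from a concentration in a cubic box
#'
#' `N = round(conc_mM * 1e-3 * N_A * V_box)` with the box volume in litres
#' (`(box_nm * 1e-8 dm)^3`). [concentration_from_count()] is the inverse.
#'
#' @param conc_mM Concentration, mM (>= 0).
#' @param box_nm Cubic box edge, nm (> 0).
#' @return Integer particle count.
#' @examples
#' count_from_concentration(2.3, 15.3)  # 5
#' count_from_concentration(4.5, 15.4)  # 10
#' @export
count_from_concentration <- function(conc_mM, box_nm) {
  stopifnot(all(conc_mM >= 0), box_nm > 0)
  V_L <- (box_nm * 1e-8)^3
  as.integer(round(conc_mM * 1e-3 * cg_constants$NA_mol * V_L))
}

#' @rdname count_from_concentration
#' @param count Particle count (>= 0).
#' @return `concentration_from_count`: concentration in mM.
#' @export
concentration_from_count <- function(count, box_nm) {
  stopifnot(all(count >= 0), box_nm > 0)
  V_L <- (box_nm * 1e-8)^3
  count / (1e-3 * cg_constants$NA_mol * V_L)
}

#' Full simulation system specification
#'
#' A cubic periodic box, a list of species with counts, the interaction
#' parameters and a temperature. Minimum-image validity requires
#' `box_nm >= 2 * cutoff_nm`; desk-scale systems may instead reduce the
#' cutoff proportionally (`allow_reduced_cutoff = TRUE` permits any cutoff
#' `<= box/2`, recorded on the returned object as a deviation from the
#' production 49.5 nm cutoff).
#'
#' @param box_nm Cubic box edge, nm.
#' @param species_list List of [species()] objects with counts set.
#' @param params [interaction_params()].
#' @param temperature_K Temperature, K.
#' @param label Free-text system label.
#' @param allow_reduced_cutoff Allow `box < 2 * cutoff` provided
#'   `cutoff <= box / 2` is enforced by reducing the cutoff.
#' @return An object of class `"system_spec"`.
#' @export
system_spec <- function(box_nm, species_list, params = interaction_params(),
                        temperature_K = 298, label = "",
                        allow_reduced_cutoff = FALSE) {
  stopifnot(box_nm > 0, length(species_list) >= 1)
  for (sp in species_list) {
    if (!inherits(sp, "cg_species")) stop("species_list must contain cg_species")
    if (is.na(sp$count)) stop("every species needs a particle count")
  }
  counts <- vapply(species_list, function(s) s$count, integer(1))
  if (sum(counts) < 1) stop("total particle count must be >= 1")
  reduced <- FALSE
  if (box_nm < 2 * params$cutoff_nm) {
    if (!allow_reduced_cutoff) {
      stop(sprintf(
        "box (%.1f nm) < 2 * cutoff (%.1f nm); set allow_reduced_cutoff = TRUE to shrink the cutoff to box/2",
        box_nm, params$cutoff_nm))
    }
    ratio <- params$switch_on_nm / params$cutoff_nm
    params$cutoff_nm <- box_nm / 2
    params$switch_on_nm <- ratio * params$cutoff_nm
    reduced <- TRUE
  }
  structure(list(
    box_nm = box_nm, species = species_list, params = params,
    temperature_K = temperature_K, label = label,
    reduced_cutoff = reduced
  ), class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  box %.2f nm, T = %g K, %d species, %d particles%s\n",
              x$box_nm, x$temperature_K, length(x$species),
              sum(vapply(x$species, function(s) s$count, integer(1))),
              if (isTRUE(x$reduced_cutoff)) " [reduced cutoff]" else ""))
  for (sp in x$species) {
    cat(sprintf("    %-12s N = %5d  r = %.2f nm  q = %+g (q_eff %+.2f)\n",
                sp$name, sp$count, sp$radius_nm, sp$nominal_charge_e,
                sp$effective_charge_e))
  }
  invisible(x)
}

# flat per-particle views used by the engine and analyses
spec_species_index <- function(spec) {
  counts <- vapply(spec$species, function(s) s$count, integer(1))
  rep(seq_along(spec$species), counts)
}

spec_pair_tables <- function(spec) {
  sig <- vapply(spec$species, function(s) s$sigma_nm, numeric(1))
  aco <- vapply(spec$species, function(s) s$A_coeff, numeric(1))
  list(sigma_ij = outer(sig, sig, "+"), A_ij = outer(aco, aco, "*"))
}

#' Build a binary RNA-protein system
#'
#' RNA is fixed to the J345 ribozyme parameters (q = -46, r = 1.47 nm);
#' the protein is looked up in [binary_species_table()].
#'
#' @param protein Protein label (see [binary_species_table()]).
#' @param rna_conc_mM,protein_conc_mM Total concentrations, mM.
#' @param box_nm Cubic box edge, nm.
#' @param params [interaction_params()].
#' @param temperature_K Temperature, K.
#' @param allow_reduced_cutoff See [system_spec()].
#' @return A [system_spec()]. If `rna_conc_mM` rounds to zero particles the
#'   system contains only the protein species (and vice versa).
#' @examples
#' build_binary("trypsin", 0.493, 0.350, box_nm = 55,
#'              params = interaction_params(kappa = 0.7),
#'              allow_reduced_cutoff = TRUE)
#' @export
build_binary <- function(protein, rna_conc_mM, protein_conc_mM, box_nm,
                         params = interaction_params(),
                         temperature_K = 298, allow_reduced_cutoff = FALSE) {
  tab <- binary_species_table()
  tab <- tab[tab$name != "RNA", ]
  if (!protein %in% tab$name) {
    stop(sprintf("unknown protein '%s'; valid labels: %s",
                 protein, paste(tab$name, collapse = ", ")))
  }
  row <- tab[tab$name == protein, ]
  n_rna <- count_from_concentration(rna_conc_mM, box_nm)
  n_pro <- count_from_concentration(protein_conc_mM, box_nm)
  sp <- list()
  if (n_rna > 0) {
    sp <- c(sp, list(species("RNA", 1.47, -46, count = n_rna,
                             charge_model = params$charge_model,
                             log_base = params$log_base)))
  }
  if (n_pro > 0) {
    sp <- c(sp, list(species(protein, row$radius_nm, row$charge_e,
                             count = n_pro,
                             charge_model = params$charge_model,
                             log_base = params$log_base)))
  }
  if (length(sp) == 0) stop("both species round to zero particles")
  system_spec(box_nm, sp, params, temperature_K,
              label = sprintf("binary RNA-%s", protein),
              allow_reduced_cutoff = allow_reduced_cutoff)
}

#' Built-in five-component species parameters
#'
#' POS_L, POS_S and CRW are fixed; tRNA and RP radii/charges must be supplied
#' by the caller since the reference cytoplasm composition is not published
#' with this package. `tRNA_example`/`RP_example` document plausible values
#' (tRNA-sized RNA and a ribosome-sized particle) used in examples and tests;
#' they are assumptions, not reference values.
#'
#' @return data.frame with columns `name`, `charge_e`, `radius_nm` and
#'   logical `fixed`.
#' @export
five_component_table <- function() {
  data.frame(
    name = c("POS_L", "POS_S", "CRW", "tRNA_example", "RP_example"),
    charge_e = c(20, 1, 0, -59, -4000),
    radius_nm = c(3.5, 2.52, 2.52, 2.0, 10.0),
    fixed = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build the reduced five-component cytoplasm system
#'
#' Components: tRNA, ribosome particles (RP), large and small positively
#' charged proteins (POS_L: q = 20, r = 3.5 nm; POS_S: q = 1, r = 2.52 nm)
#' and neutral crowders (CRW: q = 0, r = 2.52 nm). tRNA and RP parameters
#' must be supplied by the caller (`trna`, `rp`: lists with `radius_nm`,
#' `charge_e`). In `hold_volume` mode the CRW count is adjusted so the total
#' molecular volume `sum(N_i * 4/3 pi r_i^3)` matches `target_volume_nm3`
#' (used when scanning POS_L/RP concentrations at constant crowding).
#'
#' @param conc_mM Named numeric vector of concentrations in mM; names from
#'   {tRNA, RP, POS_L, POS_S, CRW}.
#' @param box_nm Cubic box edge, nm.
#' @param trna,rp Lists with elements `radius_nm` and `charge_e`.
#' @param params [interaction_params()].
#' @param temperature_K Temperature, K.
#' @param hold_volume If `TRUE`, adjust the CRW count to meet
#'   `target_volume_nm3`.
#' @param target_volume_nm3 Total molecular volume to hold, nm^3.
#' @param allow_reduced_cutoff See [system_spec()].
#' @return A [system_spec()].
#' @export
build_five_component <- function(conc_mM, box_nm,
                                 trna = list(radius_nm = 2.0, charge_e = -59),
                                 rp = list(radius_nm = 10.0, charge_e = -4000),
                                 params = interaction_params(),
                                 temperature_K = 298,
                                 hold_volume = FALSE, target_volume_nm3 = NULL,
                                 allow_reduced_cutoff = FALSE) {
  valid <- c("tRNA", "RP", "POS_L", "POS_S", "CRW")
  if (is.null(names(conc_mM)) || !all(names(conc_mM) %in% valid)) {
    stop(sprintf("conc_mM must be named with keys among: %s",
                 paste(valid, collapse = ", ")))
  }
  tab <- five_component_table()
  par_of <- function(key) {
    switch(key,
      tRNA = trna, RP = rp,
      POS_L = list(radius_nm = 3.5, charge_e = 20),
      POS_S = list(radius_nm = 2.52, charge_e = 1),
      CRW = list(radius_nm = 2.52, charge_e = 0))
  }
  counts <- vapply(names(conc_mM), function(k)
    count_from_concentration(conc_mM[[k]], box_nm), integer(1))
  if (hold_volume) {
    if (is.null(target_volume_nm3)) stop("hold_volume needs target_volume_nm3")
    vol_no_crw <- 0
    for (k in names(conc_mM)) {
      if (k == "CRW") next
      r <- par_of(k)$radius_nm
      vol_no_crw <- vol_no_crw + counts[[k]] * (4 / 3) * pi * r^3
    }
    v_crw <- (4 / 3) * pi * 2.52^3
    n_crw <- round((target_volume_nm3 - vol_no_crw) / v_crw)
    if (n_crw < 0) stop("target volume already exceeded without crowders")
    counts[["CRW"]] <- as.integer(n_crw)
    if (!"CRW" %in% names(conc_mM)) {
      conc_mM <- c(conc_mM, CRW = concentration_from_count(n_crw, box_nm))
      counts <- c(counts, CRW = as.integer(n_crw))
    }
  }
  keep <- names(conc_mM)[counts[names(conc_mM)] > 0]
  if (length(keep) == 0) stop("all species round to zero particles")
  sp <- lapply(keep, function(k) {
    p <- par_of(k)
    species(k, p$radius_nm, p$charge_e, count = counts[[k]],
            charge_model = params$charge_model, log_base = params$log_base)
  })
  system_spec(box_nm, sp, params, temperature_K,
              label = "five-component reduced cytoplasm",
              allow_reduced_cutoff = allow_reduced_cutoff)
}

#' Recipe for a seeded synthetic polydisperse cytoplasm
#'
#' Emulates a crowded bacterial cytoplasm when the exact per-molecule
#' composition is unavailable: a log-normal radius distribution over many
#' species, a charge mixture of many small positive/negative proteins, a few
#' strongly negative RNA-like species, and one very large ribosome-like
#' class, filled to a target total macromolecular volume fraction. This
#' generator is synthetic by construction; its outputs are labelled as such.
#'
#' @param n_species Number of distinct species (>= 1).
#' @param radius_meanlog,radius_sdlog Log-normal parameters for radii (nm).
#' @param frac_rna_like Fraction of species drawn as RNA-like (large
#'   negative charges, q ~ -25 to -100).
#' @param include_ribosome Add one ribosome-like species (r = 10 nm,
#'   q = -4000).
#' @param target_volume_fraction Total macromolecular volume fraction
#'   (must be <= 0.45).
#' @param box_nm Cubic box edge, nm.
#' @param seed Integer seed; identical recipes give identical systems.
#' @return An object of class `"cytoplasm_recipe"`.
#' @export
cytoplasm_recipe <- function(n_species = 12, radius_meanlog = log(2.2),
                             radius_sdlog = 0.35, frac_rna_like = 0.2,
                             include_ribosome = TRUE,
                             target_volume_fraction = 0.30,
                             box_nm = 60, seed = 1L) {
  stopifnot(n_species >= 1, target_volume_fraction > 0)
  if (target_volume_fraction > 0.45) {
    stop("target_volume_fraction > 0.45 is infeasible to pack")
  }
  structure(list(
    n_species = as.integer(n_species), radius_meanlog = radius_meanlog,
    radius_sdlog = radius_sdlog, frac_rna_like = frac_rna_like,
    include_ribosome = include_ribosome,
    target_volume_fraction = target_volume_fraction,
    box_nm = box_nm, seed = as.integer(seed)
  ), class = "cytoplasm_recipe")
}

#' Build a synthetic cytoplasm system from a recipe
#'
#' Draws per-species radii and charges from the recipe distributions
#' (deterministically under the recipe seed), then assigns counts
#' proportional to inverse particle volume until the realized total volume
#' fraction is within 1% of the target. A manifest of realized parameters is
#' attached as attribute `"manifest"` (a data.frame) together with the
#' realized volume fraction and total effective charge.
#'
#' @param recipe A [cytoplasm_recipe()].
#' @param params [interaction_params()].
#' @param temperature_K Temperature, K.
#' @return A [system_spec()] with attributes `manifest`,
#'   `realized_volume_fraction` and `total_effective_charge`.
#' @export
build_synthetic_cytoplasm <- function(recipe, params = interaction_params(),
                                      temperature_K = 298) {
  stopifnot(inherits(recipe, "cytoplasm_recipe"))
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(recipe$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    n <- recipe$n_species
    radii <- stats::rlnorm(n, recipe$radius_meanlog, recipe$radius_sdlog)
    radii <- pmin(pmax(radii, 0.8), 6)
    n_rna <- max(if (recipe$frac_rna_like > 0) 1L else 0L,
                 round(recipe$frac_rna_like * n))
    kind <- c(rep("rna", n_rna), rep("protein", n - n_rna))
    charges <- numeric(n)
    charges[kind == "rna"] <- -round(stats::runif(n_rna, 25, 100))
    charges[kind == "protein"] <- round(stats::rnorm(n - n_rna, 2, 6))
    list(radii = radii, charges = charges)
  })
  radii <- rng$radii
  charges <- rng$charges
  names_sp <- sprintf("SYN%02d", seq_along(radii))
  if (recipe$include_ribosome) {
    radii <- c(radii, 10)
    charges <- c(charges, -4000)
    names_sp <- c(names_sp, "SYN_RIBO")
  }
  vbox <- recipe$box_nm^3
  vpart <- (4 / 3) * pi * radii^3
  # equal volume share per species, ribosome capped to a handful of copies
  share <- rep(1, length(radii))
  if (recipe$include_ribosome) share[length(share)] <- 0.5
  share <- share / sum(share)
  target_v <- recipe$target_volume_fraction * vbox
  counts <- pmax(0L, as.integer(round(share * target_v / vpart)))
  counts[counts == 0 & share > 0] <- 1L
  # trim/raise the most numerous species to land within +-1% of target
  realized <- sum(counts * vpart)
  j <- which.max(counts)
  counts[j] <- counts[j] + round((target_v - realized) / vpart[j])
  counts[j] <- max(counts[j], 0L)
  keep <- counts > 0
  sp <- lapply(which(keep), function(i) {
    species(names_sp[i], radii[i], charges[i], count = counts[i],
            charge_model = params$charge_model, log_base = params$log_base)
  })
  spec <- system_spec(recipe$box_nm, sp, params, temperature_K,
                      label = sprintf("synthetic cytoplasm (seed %d)", recipe$seed),
                      allow_reduced_cutoff = TRUE)
  manifest <- data.frame(
    name = names_sp[keep], radius_nm = radii[keep], charge_e = charges[keep],
    effective_charge_e = vapply(sp, function(s) s$effective_charge_e, numeric(1)),
    count = counts[keep], stringsAsFactors = FALSE
  )
  phi <- sum(counts[keep] * vpart[keep]) / vbox
  if (abs(phi - recipe$target_volume_fraction) > 0.01) {
    stop(sprintf("realized volume fraction %.3f misses target %.3f by > 0.01",
                 phi, recipe$target_volume_fraction))
  }
  attr(spec, "manifest") <- manifest
  attr(spec, "realized_volume_fraction") <- phi
  attr(spec, "total_effective_charge") <-
    sum(manifest$effective_charge_e * manifest$count)
  spec
}

#' Compact-droplet initial placement
#'
#' Places all particles without overlap inside a ball at the box centre
#' (direct-coexistence style start). A desk-scale run started this way
#' probes condensate stability: a phase-separating system keeps most
#' particles in one large cluster, a non-separating one evaporates into
#' the dilute phase. Nucleation from uniform random starts takes orders of
#' magnitude longer than desk-scale runs can cover.
#'
#' @param spec A [system_spec()].
#' @param seed Integer seed.
#' @param radius_nm Droplet radius; default packs the particles at ~20%
#'   volume fraction.
#' @param max_tries Attempts per particle.
#' @return N x 3 coordinate matrix (nm).
#' @export
droplet_placement <- function(spec, seed = 1L, radius_nm = NULL,
                              max_tries = 20000L) {
  idx <- spec_species_index(spec)
  n <- length(idx)
  tabs <- spec_pair_tables(spec)
  radii <- vapply(spec$species, function(s) s$radius_nm, numeric(1))
  if (is.null(radius_nm)) {
    vtot <- sum((4 / 3) * pi * radii[idx]^3)
    radius_nm <- (vtot / 0.20 / ((4 / 3) * pi))^(1 / 3)
  }
  if (2 * radius_nm > spec$box_nm) stop("droplet larger than the box")
  centre <- rep(spec$box_nm / 2, 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  order_i <- order(radii[idx], decreasing = TRUE)
  coords <- matrix(NA_real_, n, 3)
  placed <- integer(0)
  for (i in order_i) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      u <- stats::runif(3, -radius_nm, radius_nm)
      if (sqrt(sum(u^2)) > radius_nm) next
      x <- centre + u
      if (length(placed) == 0) { ok <- TRUE; break }
      d <- sweep(coords[placed, , drop = FALSE], 2, x)
      d <- d - spec$box_nm * round(d / spec$box_nm)
      if (all(sqrt(rowSums(d^2)) >= tabs$sigma_ij[idx[placed], idx[i]])) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("droplet placement failed (placed %d of %d); increase radius_nm",
                   length(placed), n))
    }
    coords[i, ] <- x
    placed <- c(placed, i)
  }
  coords
}

#' Random non-overlapping initial placement
#'
#' Places all particles uniformly in the periodic box, rejecting positions
#' whose minimum-image distance to an already placed particle is below
#' `sigma_ij` (particles at contact or beyond are accepted). Deterministic
#' under `seed`.
#'
#' @param spec A [system_spec()].
#' @param seed Integer seed.
#' @param max_tries Placement attempts per particle before giving up.
#' @return N x 3 matrix of coordinates in `[0, box)` nm.
#' @export
random_placement <- function(spec, seed = 1L, max_tries = 2000L) {
  idx <- spec_species_index(spec)
  n <- length(idx)
  tabs <- spec_pair_tables(spec)
  box <- spec$box_nm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  # place large particles first: easier packing
  radii <- vapply(spec$species, function(s) s$radius_nm, numeric(1))[idx]
  order_i <- order(radii, decreasing = TRUE)
  coords <- matrix(NA_real_, n, 3)
  placed <- integer(0)
  for (i in order_i) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(3, 0, box)
      if (length(placed) == 0) { ok <- TRUE; break }
      d <- sweep(coords[placed, , drop = FALSE], 2, x)
      d <- d - box * round(d / box)
      dist <- sqrt(rowSums(d^2))
      if (all(dist >= tabs$sigma_ij[idx[placed], idx[i]])) { ok <- TRUE; break }
    }
    if (!ok) {
      stop(sprintf("placement failed after %d tries (placed %d of %d particles); packing too dense",
                   max_tries, length(placed), n))
    }
    coords[i, ] <- x
    placed <- c(placed, i)
  }
  coords
}
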