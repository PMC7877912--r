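# Shared fixtures: all built in code at test time.

# desk-scale binary system: production concentrations, reduced box/cutoff
desk_binary <- function(protein = "trypsin", box_nm = 55, kappa = 0.7,
                        cutoff_nm = 12) {
  p <- interaction_params(kappa = kappa, cutoff_nm = cutoff_nm,
                          switch_on_nm = cutoff_nm - 0.5,
                          charge_model = "eq5")
  build_binary(protein, 0.493, 0.350, box_nm, p)
}

# direct-coexistence desk run: compact droplet start, then Langevin
desk_condensation_run <- function(protein, n_steps = 500000L, seed = 4L) {
  spec <- desk_binary(protein)
  co <- droplet_placement(spec, seed = 9L, radius_nm = 15)
  sp <- simulation_params(n_steps = n_steps, save_interval_steps = 20000L,
                          seed = seed)
  run_simulation(spec, co, sp)
}

rna_protein_criterion <- function(protein) {
  contact_criterion(2.2, pair_classes = list(list(A = "RNA", B = protein)))
}

# tiny gofr library with analytic tables, for theory unit tests
flat_gofr_library <- function(g_value = 1) {
  r <- seq(0, 20, by = 0.25)
  tb <- data.frame(r_nm = r, g = rep(g_value, length(r)))
  tabs <- list()
  for (p in c("RR", "RP", "PP")) {
    tabs[[p]] <- list(dilute = tb, condensed = tb, disperse = tb)
  }
  gofr_library(tabs, r_R_MD = 1.47, r_P_MD = 1.81, trunc_nm = 20)
}

# the packaged reference library (read once per test file)
packaged_gofr <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- default_gofr_library()
    lib
  }
})

# straight-line transcription of the pair interaction (independent oracle,
# written directly from the energy expression, no switching below switch-on)
oracle_pair_energy <- function(r, sigma_ij, A_ij, eps = 4, A0 = 3,
                               kappa = 1.5) {
  4 * eps * ((sigma_ij / r)^10 - (sigma_ij / r)^5) +
    (A_ij + A0) * (kappa * sigma_ij / r) * exp(-r / (kappa * sigma_ij))
}

# brute-force transitive closure clustering (independent oracle)
oracle_clusters <- function(edges, n) {
  adj <- diag(TRUE, n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[adj[i, ]] <- lab
    }
  }
  labels
}
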