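test_that("particle counts from concentrations match the validation boxes", {
  expect_identical(count_from_concentration(2.3, 15.3), 5L)
  expect_identical(count_from_concentration(4.5, 15.4), 10L)
  expect_identical(count_from_concentration(0, 20), 0L)
})

test_that("count <-> concentration round trip is consistent to one particle", {
  for (box in c(15.3, 55, 100)) {
    for (n in c(1L, 7L, 50L, 480L)) {
      c_mM <- concentration_from_count(n, box)
      expect_equal(count_from_concentration(c_mM, box), n)
    }
  }
})

test_that("built-in binary species table matches the published parameters", {
  tab <- binary_species_table()
  get <- function(nm) unlist(tab[tab$name == nm, c("charge_e", "radius_nm")])
  expect_equal(unname(get("RNA")), c(-46, 1.47))
  expect_equal(unname(get("trypsin")), c(6, 1.81))
  expect_equal(unname(get("ADH")), c(8, 2.79))
  expect_equal(unname(get("myoglobin")), c(2, 1.64))
  expect_equal(unname(get("lysozyme")), c(8, 1.54))
  expect_equal(unname(get("cytochromeC")), c(11, 1.45))
  expect_equal(unname(get("LDH")), c(4, 2.68))
  expect_equal(unname(get("BSA")), c(-17, 2.58))
})

test_that("binary builder resolves proteins and handles edge cases", {
  spec <- build_binary("trypsin", 0.493, 0.350, 55,
                       interaction_params(kappa = 0.7),
                       allow_reduced_cutoff = TRUE)
  nm <- vapply(spec$species, function(s) s$name, character(1))
  expect_setequal(nm, c("RNA", "trypsin"))
  expect_error(build_binary("elastase", 0.4, 0.3, 55), "lysozyme")
  solo <- build_binary("trypsin", 0, 0.35, 55, allow_reduced_cutoff = TRUE)
  expect_length(solo$species, 1)
  expect_identical(solo$species[[1]]$name, "trypsin")
})

test_that("system_spec enforces the minimum-image box unless cutoff shrinks", {
  sp <- list(species("A", 2, 0, count = 10))
  expect_error(system_spec(50, sp, interaction_params()), "cutoff")
  spec <- system_spec(50, sp, interaction_params(), allow_reduced_cutoff = TRUE)
  expect_lte(spec$params$cutoff_nm, 25)
  expect_lt(spec$params$switch_on_nm, spec$params$cutoff_nm)
})

test_that("five-component builder: lookups, volume hold, degenerate input", {
  tab <- five_component_table()
  expect_equal(unlist(tab[tab$name == "POS_L", c("charge_e", "radius_nm")]),
               c(charge_e = 20, radius_nm = 3.5))
  expect_equal(unlist(tab[tab$name == "POS_S", c("charge_e", "radius_nm")]),
               c(charge_e = 1, radius_nm = 2.52))
  expect_equal(unlist(tab[tab$name == "CRW", c("charge_e", "radius_nm")]),
               c(charge_e = 0, radius_nm = 2.52))

  base <- build_five_component(
    c(tRNA = 0.4, RP = 0.055, POS_L = 0.18, POS_S = 0.4, CRW = 1.2),
    box_nm = 60, allow_reduced_cutoff = TRUE)
  vol_of <- function(spec) {
    sum(vapply(spec$species,
               function(s) s$count * (4 / 3) * pi * s$radius_nm^3, numeric(1)))
  }
  v0 <- vol_of(base)
  # raising POS_L under volume hold lowers CRW; total volume within 0.5%
  up <- build_five_component(
    c(tRNA = 0.4, RP = 0.055, POS_L = 0.28, POS_S = 0.4, CRW = 1.2),
    box_nm = 60, hold_volume = TRUE, target_volume_nm3 = v0,
    allow_reduced_cutoff = TRUE)
  expect_lt(abs(vol_of(up) - v0) / v0, 0.005)
  n_crw <- function(spec) {
    i <- which(vapply(spec$species, function(s) s$name, character(1)) == "CRW")
    spec$species[[i]]$count
  }
  expect_lt(n_crw(up), n_crw(base))
  expect_error(build_five_component(c(tRNA = 0, RP = 0), box_nm = 60), "zero")
  expect_error(build_five_component(c(foo = 1), box_nm = 60), "keys")
})

test_that("synthetic cytoplasm is seeded-reproducible and hits its volume target", {
  rec <- cytoplasm_recipe(n_species = 8, target_volume_fraction = 0.30,
                          box_nm = 50, seed = 11)
  a <- build_synthetic_cytoplasm(rec)
  b <- build_synthetic_cytoplasm(rec)
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))
  expect_gte(attr(a, "realized_volume_fraction"), 0.29)
  expect_lte(attr(a, "realized_volume_fraction"), 0.31)
  expect_true(is.finite(attr(a, "total_effective_charge")))
  # one-species recipe degenerates to a monodisperse system
  rec1 <- cytoplasm_recipe(n_species = 1, frac_rna_like = 0,
                           include_ribosome = FALSE,
                           target_volume_fraction = 0.2, box_nm = 40,
                           seed = 3)
  mono <- build_synthetic_cytoplasm(rec1)
  expect_length(mono$species, 1)
  expect_error(cytoplasm_recipe(target_volume_fraction = 0.6), "infeasible")
})

test_that("random placement avoids overlap, is seeded, and fails when impossible", {
  spec <- system_spec(30, list(species("A", 1.5, 0, count = 40)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  co1 <- random_placement(spec, seed = 5)
  co2 <- random_placement(spec, seed = 5)
  expect_identical(co1, co2)
  idx <- coacerv:::spec_species_index(spec)
  sig <- coacerv:::spec_pair_tables(spec)$sigma_ij
  d <- coacerv:::min_image_dist(co1, spec$box_nm)
  diag(d) <- Inf
  expect_true(all(d >= sig[idx, idx]))
  expect_true(all(co1 >= 0 & co1 < spec$box_nm))
  # volume fraction near 0.9 cannot be packed
  dense <- system_spec(6, list(species("A", 1.5, 0, count = 150)),
                       interaction_params(), allow_reduced_cutoff = TRUE)
  expect_error(random_placement(dense, seed = 1, max_tries = 200L), "failed")
})

test_that("droplet placement packs all particles inside the requested ball", {
  spec <- desk_binary("trypsin")
  co <- droplet_placement(spec, seed = 9, radius_nm = 15)
  centre <- rep(spec$box_nm / 2, 3)
  dist <- sqrt(rowSums(sweep(co, 2, centre)^2))
  expect_true(all(dist <= 15 + 1e-9))
  idx <- coacerv:::spec_species_index(spec)
  sig <- coacerv:::spec_pair_tables(spec)$sigma_ij
  d <- coacerv:::min_image_dist(co, spec$box_nm)
  diag(d) <- Inf
  expect_true(all(d >= sig[idx, idx]))
})
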