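two_particle_spec <- function(box = 30, r1 = 1.5, r2 = 1.5) {
  system_spec(box, list(species("A", r1, 0, count = 1),
                        species("B", r2, 0, count = 1)),
              interaction_params(), allow_reduced_cutoff = TRUE)
}

test_that("contact criterion is a strict inequality at sigma_ij + delta", {
  spec <- two_particle_spec()
  sig <- coacerv:::spec_pair_tables(spec)$sigma_ij[1, 2]
  crit <- contact_criterion(0.7)
  at <- rbind(c(5, 5, 5), c(5 + sig + 0.7, 5, 5))
  just_in <- rbind(c(5, 5, 5), c(5 + sig + 0.7 - 1e-6, 5, 5))
  expect_identical(nrow(contact_graph(at, spec, crit)), 0L)
  expect_identical(nrow(contact_graph(just_in, spec, crit)), 1L)
})

test_that("pair classes restrict which species pairs form edges", {
  spec <- system_spec(30, list(species("tRNA", 2, -59, count = 2),
                               species("POS", 2.5, 10, count = 1)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  # two adjacent tRNAs plus one POS next to a tRNA
  fr <- rbind(c(5, 5, 5), c(9, 5, 5), c(5, 9.2, 5))
  all_pairs <- contact_graph(fr, spec, contact_criterion(2.2))
  expect_gte(nrow(all_pairs), 2)
  only_cross <- contact_graph(fr, spec, contact_criterion(
    2.2, pair_classes = list(list(A = "tRNA", B = "POS"))))
  idx <- coacerv:::spec_species_index(spec)
  expect_true(all(idx[only_cross[, 1]] != idx[only_cross[, 2]]))
})

test_that("connected clusters partition particles and match transitive closure", {
  # hand-built chain
  cs <- connected_clusters(rbind(c(1L, 2L), c(2L, 3L)), 1:4)
  expect_identical(cs$sizes, c(3L, 1L))
  expect_setequal(cs$clusters[[1]], 1:3)
  none <- connected_clusters(matrix(integer(0), 0, 2), 1:5)
  expect_identical(none$sizes, rep(1L, 5))
  # random graphs vs brute-force closure
  set.seed(99)
  for (rep in 1:25) {
    n <- 50L
    m <- sample(0:60, 1)
    edges <- if (m > 0) {
      e <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      t(apply(e, 1, sort))
    } else matrix(integer(0), 0, 2)
    storage.mode(edges) <- "integer"
    cs <- connected_clusters(edges, 1:n)
    lab <- oracle_clusters(edges, n)
    # same partition: identical co-membership matrices
    memb <- cs$membership[order(as.integer(names(cs$membership)))]
    got <- unname(outer(unname(memb), unname(memb), "=="))
    want <- outer(lab, lab, "==")
    expect_identical(got, want)
    expect_identical(sum(cs$sizes), n)
  }
})

test_that("condensate volume: closed-form sphere cases and voxel cross-check", {
  spec <- system_spec(60, list(species("A", 1, 0, count = 3)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  fr <- rbind(c(10, 10, 10), c(40, 40, 40), c(10, 10, 10))
  v1 <- condensate_volume(fr, 1L, spec, probe_nm = 2.2, seed = 2)
  v_exact <- (4 / 3) * pi * 3.2^3
  expect_equal(as.numeric(v1), v_exact, tolerance = 0.03)
  v2 <- condensate_volume(fr, c(1L, 2L), spec, probe_nm = 2.2, seed = 3)
  expect_equal(as.numeric(v2), 2 * v_exact, tolerance = 0.03)
  v3 <- condensate_volume(fr, c(1L, 3L), spec, probe_nm = 2.2, seed = 4)
  expect_equal(as.numeric(v3), v_exact, tolerance = 0.03)
  # MC vs voxel grid on random clusters
  set.seed(7)
  spec2 <- system_spec(40, list(species("A", 1.4, 0, count = 12)),
                       interaction_params(), allow_reduced_cutoff = TRUE)
  for (k in 1:5) {
    fr2 <- matrix(runif(36, 15, 25), 12, 3)
    vm <- condensate_volume(fr2, 1:12, spec2, seed = k)
    vv <- condensate_volume_voxel(fr2, 1:12, spec2, voxel_nm = 0.25)
    expect_equal(as.numeric(vm), vv, tolerance = 0.02)
  }
})

test_that("rdf is 1 for ideal gas, 0 inside the core, density-invariant", {
  # ideal-gas oracle: Poisson-placed particles
  set.seed(21)
  box <- 30
  mk_traj <- function(n, nf = 100) {
    frames <- array(runif(n * 3 * nf, 0, box), c(n, 3, nf))
    structure(list(frames = frames, times_ns = seq_len(nf),
                   species_index = rep(1L, n), species_names = "A",
                   box_nm = box, spec = NULL,
                   potential_kJmol = rep(NA_real_, nf),
                   kinetic_kJmol = rep(NA_real_, nf)),
              class = "cg_trajectory")
  }
  tr <- mk_traj(200)
  g <- rdf(tr, "A", "A", bin_nm = 0.5)
  far <- g$g[g$r_nm > 1]
  expect_true(all(abs(far - 1) < 0.05))
  expect_error(rdf(tr, "A", "A", bin_nm = 10), "box/4")
  # overlap-free configuration has g = 0 below contact
  spec <- system_spec(30, list(species("A", 1.5, 0, count = 40)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  co <- random_placement(spec, seed = 2)
  tr2 <- structure(list(frames = array(co, c(40, 3, 1)), times_ns = 0,
                        species_index = rep(1L, 40), species_names = "A",
                        box_nm = 30, spec = spec,
                        potential_kJmol = NA_real_, kinetic_kJmol = NA_real_),
                   class = "cg_trajectory")
  g2 <- rdf(tr2, "A", "A", bin_nm = 0.2)
  sig <- 2 * sigma_from_radius(1.5)
  expect_true(all(g2$g[g2$r_nm < sig - 0.2] == 0))
  # doubling the count at fixed box leaves g(r) unchanged within noise
  g_many <- rdf(mk_traj(400), "A", "A", bin_nm = 0.5)
  expect_lt(mean(abs(g_many$g[g_many$r_nm > 1] - far)), 0.05)
})

test_that("phase fractions recover a constructed dense-slab/dilute-gas split", {
  # construct: 60 particles in a compact ball (condensate), 6 dispersed
  box <- 60
  spec <- system_spec(box, list(species("A", 1.5, -20, count = 66)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  set.seed(5)
  dense <- matrix(NA_real_, 60, 3)
  n <- 0
  while (n < 60) {
    x <- runif(3, -8, 8)
    if (sqrt(sum(x^2)) > 8) next
    if (n > 0 && min(sqrt(rowSums(sweep(dense[1:n, , drop = FALSE], 2, x + 30)^2))) < 2.7) next
    n <- n + 1
    dense[n, ] <- x + 30
  }
  sparse <- cbind(runif(6, 0, 60), runif(6, 0, 60), c(5, 55, 5, 55, 5, 55))
  fr <- rbind(dense, sparse)
  tr <- structure(list(frames = array(fr, c(66, 3, 1)), times_ns = 0,
                       species_index = rep(1L, 66), species_names = "A",
                       box_nm = box, spec = spec,
                       potential_kJmol = NA_real_, kinetic_kJmol = NA_real_),
                  class = "cg_trajectory")
  pf <- phase_fractions(tr, "A", contact_criterion(2.2), seed = 8)
  expect_true(pf$ps_flag)
  row <- pf$per_frame[1, ]
  expect_equal(row$n_in, 60)
  # known construction: phi_H ~ 60 spheres in the condensate volume
  v_sphere <- (4 / 3) * pi * 1.5^3
  phi_H_expected <- 60 * v_sphere / row$v_condensed_nm3
  expect_equal(row$phi_H, phi_H_expected, tolerance = 1e-6)
  expect_equal(row$phi_L, 6 * v_sphere / (box^3 - row$v_condensed_nm3),
               tolerance = 1e-6)
  expect_gt(row$phi_H, row$phi_L)
})

test_that("no clusters means no phase separation and absent phi_H", {
  spec <- system_spec(60, list(species("A", 1.5, 0, count = 5)),
                      interaction_params(), allow_reduced_cutoff = TRUE)
  fr <- cbind(seq(5, 55, length.out = 5), 30, 30)
  tr <- structure(list(frames = array(fr, c(5, 3, 1)), times_ns = 0,
                       species_index = rep(1L, 5), species_names = "A",
                       box_nm = 60, spec = spec,
                       potential_kJmol = NA_real_, kinetic_kJmol = NA_real_),
                  class = "cg_trajectory")
  pf <- phase_fractions(tr, "A", contact_criterion(2.2))
  expect_false(pf$ps_flag)
  expect_true(is.na(pf$per_frame$phi_H[1]))
})

test_that("critical-point fit recovers synthetic parameters and fixes the exponent", {
  set.seed(31)
  Tc <- 450; A <- 0.1; phic <- 0.05; B <- 1e-4
  T_K <- seq(300, 440, by = 10)
  dphi <- A * (Tc - T_K)^0.32
  mid <- phic + B * (T_K - Tc)
  noise <- function(x) x * (1 + rnorm(length(x), 0, 0.01))
  df <- data.frame(T_K = T_K, phi_H = noise(mid + dphi / 2),
                   phi_L = noise(mid - dphi / 2))
  fit <- fit_critical_point(df)
  expect_lt(abs(fit$Tc_K - Tc), 5)
  expect_equal(fit$amplitude_A, A, tolerance = 0.1)
  expect_equal(fit$phi_c, phic, tolerance = 0.2)
  # exact data at T = Tc gives dphi = 0 by construction of the fitted form
  expect_equal(A * (Tc - Tc)^0.32, 0)
  expect_error(fit_critical_point(df[1:2, ]), ">= 4")
})
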