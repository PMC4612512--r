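test_that("tabular A-matrix reproduces textbook relationships", {
  two <- tibble::tibble(individual_id = c("a", "b"),
                        sire_id = c(NA, NA), dam_id = c(NA, NA))
  expect_equal(unname(build_A_matrix(two)), diag(2))

  ped <- tibble::tibble(
    individual_id = c("s", "d1", "d2", "x", "y", "z"),
    sire_id = c(NA, NA, NA, "s", "s", "s"),
    dam_id = c(NA, NA, NA, "d1", "d1", "d2"))
  A <- build_A_matrix(ped)
  expect_equal(A["x", "y"], 0.5)   # full sibs
  expect_equal(A["x", "z"], 0.25)  # paternal half sibs
  expect_equal(A["x", "s"], 0.5)   # parent-offspring
  expect_equal(unname(diag(A)), rep(1, 6))

  # sire-daughter mating: offspring inbred, diagonal 1.25
  inb <- tibble::tibble(
    individual_id = c("p1", "p2", "c", "g"),
    sire_id = c(NA, NA, "p1", "p1"),
    dam_id = c(NA, NA, "p2", "c"))
  expect_equal(build_A_matrix(inb)["g", "g"], 1.25)
})

test_that("A-matrix equals the brute-force kinship recursion on a 12-individual pedigree", {
  ped <- pedigree_12()
  A <- build_A_matrix(ped)
  A_oracle <- kinship_A_oracle(ped)
  expect_equal(A, A_oracle, tolerance = 1e-12)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_true(all(diag(A) >= 1))
})

test_that("pedigree defects are caught", {
  cyc <- tibble::tibble(individual_id = c("a", "b"),
                        sire_id = c("b", "a"), dam_id = c(NA, NA))
  expect_error(build_A_matrix(cyc), "cycle")
  dup <- tibble::tibble(individual_id = c("a", "a"),
                        sire_id = c(NA, NA), dam_id = c(NA, NA))
  expect_error(build_A_matrix(dup), "duplicated")
  orphanref <- tibble::tibble(individual_id = c("a", "b"),
                              sire_id = c(NA, "ghost"), dam_id = c(NA, NA))
  expect_warning(Ao <- build_A_matrix(orphanref), "unknown founders")
  expect_equal(unname(Ao), diag(2))
})

test_that("univariate animal likelihood matches the dense oracle", {
  cfg <- sim_config(n_sires = 5, n_dams_per_sire = 2, n_daughters_per_dam = 4,
                    seed = 107)
  sim <- simulate_dataset(cfg)
  A <- build_A_matrix(sim$pedigree)
  g <- simulate_gaussian_traits(cfg, seed = 108)
  X <- cbind(1, g$y2)
  Ao <- A[g$female_id, g$female_id]
  for (th in list(c(30, 50), c(5, 20), c(0, 40))) {
    ll <- reml_loglik_animal(th[1], th[2], g$y1, X, A, ids = g$female_id)
    ll_dense <- dense_reml_oracle(th[1] * Ao + th[2] * diag(nrow(Ao)), g$y1, X)
    expect_equal(ll, ll_dense, tolerance = 1e-8)
  }
})

test_that("univariate animal model recovers boundary and interior truths", {
  cfg0 <- sim_config(n_sires = 60, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                     G = matrix(c(0, 0, 0, 0.2), 2), V_dam = c(0, 0),
                     V_resid = c(60, 0.4), seed = 109)
  ped <- simulate_dataset(cfg0)$pedigree
  A <- build_A_matrix(ped)
  g <- simulate_gaussian_traits(cfg0, seed = 110)
  fit0 <- fit_univariate_animal_model(g, "y1", A)
  expect_lt(fit0$V_A, 0.05 * (fit0$V_A + fit0$V_resid))
})

test_that("animal-model V_A and 4*V_sire from the sire model agree at large n", {
  cfg <- sim_config(n_sires = 300, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    G = matrix(c(50, 0, 0, 0.5), 2), V_dam = c(0, 0.1),
                    V_resid = c(50, 0.4), seed = 113)
  ped <- simulate_dataset(cfg)$pedigree
  A <- build_A_matrix(ped)
  g <- simulate_gaussian_traits(cfg, seed = 114)
  fit_a <- fit_univariate_animal_model(g, "y1", A)
  fit_s <- fit_nested_lmm(dplyr::rename(g, y = y1), "y")
  V_P <- fit_s$V_sire + fit_s$V_dam + fit_s$V_resid
  expect_lt(abs(fit_a$V_A - 4 * fit_s$V_sire) / V_P, 0.1)
  expect_lt(abs(fit_a$V_A - cfg$G[1, 1]) / cfg$G[1, 1], 0.35)
})

test_that("genetic correlation obeys its algebraic identities", {
  expect_identical(genetic_correlation(0, 1, 1), 0)
  expect_identical(genetic_correlation(-0.5, 1, 1), -0.5)
  for (v in list(c(2, 3), c(50, 0.5), c(0.01, 7))) {
    expect_equal(genetic_correlation(-0.651 * sqrt(v[1] * v[2]), v[1], v[2]),
                 -0.651, tolerance = 1e-12)
  }
  expect_warning(r <- genetic_correlation(2, 1, 1), "clipped")
  expect_identical(r, 1)
  expect_error(genetic_correlation(0.5, 0, 1), "positive")
})

test_that("bivariate likelihood matches the dense oracle on a small pedigree", {
  cfg <- sim_config(n_sires = 4, n_dams_per_sire = 2, n_daughters_per_dam = 3,
                    seed = 127)
  sim <- simulate_dataset(cfg)
  A <- build_A_matrix(sim$pedigree)
  g <- simulate_gaussian_traits(cfg, seed = 128)
  n <- nrow(g)
  X1 <- matrix(1, n)
  X2 <- cbind(1, g$y1)
  G <- matrix(c(30, -2, -2, 0.4), 2)
  R <- matrix(c(40, 1, 1, 0.5), 2)
  ll <- biv_reml_loglik(G, R, g$y1, g$y2, X1, X2, A, ids = g$female_id)
  Ao <- A[g$female_id, g$female_id]
  Xb <- rbind(cbind(X1, matrix(0, n, 2)), cbind(matrix(0, n, 1), X2))
  ll_dense <- dense_reml_oracle(biv_V(G, R, Ao), c(g$y1, g$y2), Xb)
  expect_equal(ll, ll_dense, tolerance = 1e-8)
})

test_that("independently simulated traits yield a genetic correlation near zero", {
  cfg <- sim_config(n_sires = 40, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    G = matrix(c(50, 0, 0, 0.5), 2), V_dam = c(0, 0),
                    V_resid = c(50, 0.5), seed = 131)
  ped <- simulate_dataset(cfg)$pedigree
  A <- build_A_matrix(ped)
  g <- simulate_gaussian_traits(cfg, seed = 132)
  bf <- fit_bivariate_animal_model(g, c("y1", "y2"), A)
  expect_true(bf$converged)
  expect_lt(abs(bf$r_g), 2.5 * bf$se_r_g + 0.05)
  td <- tidy(bf)
  expect_identical(td$term[7], "r_g")
  expect_equal(td$estimate[7], bf$r_g)
})

test_that("the optional dam random effect fits and reports a PSD D", {
  cfg <- sim_config(n_sires = 10, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    V_dam = c(8, 0.15), V_resid = c(42, 0.35),
                    beta_lifetime_matings = 0, attrition_prob = 0, seed = 137)
  sim <- simulate_dataset(cfg)
  A <- build_A_matrix(sim$pedigree)
  g <- simulate_gaussian_traits(cfg, seed = 138)
  bf <- fit_bivariate_animal_model(g, c("y1", "y2"), A, dam_random = TRUE)
  expect_true(bf$converged)
  expect_false(is.null(bf$D))
  expect_gte(min(eigen(bf$D, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_true(abs(bf$r_g) <= 1)
})
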