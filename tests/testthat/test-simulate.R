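test_that("identical seed and config give bit-identical tables", {
  cfg <- sim_config(n_sires = 8, seed = 101)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- simulate_dataset(cfg, seed = 102)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("breeding values honour degenerate genetic architectures", {
  cfg0 <- sim_config(n_sires = 5, G = matrix(0, 2, 2), seed = 1)
  bv <- sample_breeding_values(cfg0)
  expect_true(all(bv$a1 == 0) && all(bv$a2 == 0))

  cfg_ind <- sim_config(n_sires = 300, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                        G = diag(c(40, 0.12)), seed = 2)
  bvi <- sample_breeding_values(cfg_ind)
  expect_lt(abs(cor(bvi$a1, bvi$a2)), 0.06)
})

test_that("half-sib and full-sib breeding-value covariances match G/4 and G/2", {
  cfg <- sim_config(n_sires = 500, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    G = diag(c(40, 0.12)), seed = 3)
  bv <- sample_breeding_values(cfg)
  vc <- anova_oracle_balanced(bv$a1, bv$sire_id, bv$dam_id)
  # Monte-Carlo SDs of the moment estimators at 500 sires are about 1.0,
  # 0.76 and 0.5 (from the mean-square sampling variances); allow 3 SDs.
  # between-sire variance of breeding values = half-sib covariance = G11/4
  expect_lt(abs(vc$V_sire - 10), 3)
  # between-dam-within-sire adds another G11/4 (full sibs share G11/2)
  expect_lt(abs(vc$V_dam - 10), 2.3)
  expect_lt(abs(vc$V_resid - 20), 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(G = matrix(c(1, 2, 2, 1), 2)), "positive semidefinite")
  expect_error(sim_config(G = matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(sim_config(V_dam = c(-1, 0)), "non-negative")
  expect_error(sim_config(trait_means = c(-5, 0)), "positive")
  expect_error(sim_config(n_sires = 0), "positive")
})

test_that("simulated records are internally consistent", {
  cfg <- sim_config(n_sires = 10, seed = 7)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes

  expect_true(all(ph$longevity >= 1))
  expect_true(all(grepl("^[01]*$", ph$mating_outcomes)))
  expect_identical(ph$n_opportunities, nchar(ph$mating_outcomes))

  # opportunity count consistent with longevity under the 2-2-3 schedule
  days <- cumsum(c(cfg$first_opportunity_day,
                   rep_len(cfg$opportunity_schedule, 60)))
  n_opp <- vapply(ph$longevity, function(L) sum(days <= L), integer(1))
  expect_identical(ph$n_opportunities, n_opp)

  # pedigree soundness: founders first with missing parents, every parent listed
  ped <- sim$pedigree
  founders <- ped$individual_id[is.na(ped$sire_id)]
  expect_true(all(stats::na.omit(ped$sire_id) %in% founders))
  expect_true(all(stats::na.omit(ped$dam_id) %in% founders))
  expect_true(all(ph$sire_id %in% founders) && all(ph$dam_id %in% founders))

  # manifest truths recomputable from the configuration
  expect_equal(sim$truth$true_h2,
               diag(cfg$G) / (diag(cfg$G) + cfg$V_dam + cfg$V_resid))
  expect_equal(sim$truth$true_r_g,
               cfg$G[1, 2] / sqrt(cfg$G[1, 1] * cfg$G[2, 2]))
})

test_that("attrition flags and degenerate variance cases behave as declared", {
  sim0 <- simulate_dataset(sim_config(n_sires = 8, attrition_prob = 0, seed = 11))
  expect_true(all(sim0$phenotypes$death_cause == "natural"))

  sim1 <- simulate_dataset(sim_config(n_sires = 30, attrition_prob = 1, seed = 12))
  expect_true(all(sim1$phenotypes$death_cause %in% c("escaped", "accidental")))

  cfg_det <- sim_config(n_sires = 4, G = matrix(0, 2, 2), V_dam = c(0, 0),
                        V_resid = c(0, 0), beta_lifetime_matings = 0,
                        beta_start_date = 0, seed = 13)
  simd <- simulate_dataset(cfg_det)
  expect_length(unique(simd$phenotypes$longevity), 1L)
})

test_that("sire-family intraclass correlation of longevity tracks h2/4", {
  cfg <- sim_config(n_sires = 500, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    beta_lifetime_matings = 0, beta_start_date = 0,
                    attrition_prob = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  vc <- anova_oracle_balanced(ph$longevity, ph$sire_id, ph$dam_id)
  icc <- vc$V_sire / (vc$V_sire + vc$V_dam + vc$V_resid)
  # Monte-Carlo SE of the sire ICC is ~0.012 at 500 sires; allow 3 SEs
  expect_lt(abs(icc - sim$truth$true_h2[1] / 4), 0.036)
})

test_that("Gaussian-trait generator reproduces the configured architecture", {
  cfg <- sim_config(n_sires = 500, n_dams_per_sire = 3, n_daughters_per_dam = 3,
                    V_dam = c(5, 0.1), seed = 19)
  g <- simulate_gaussian_traits(cfg)
  expect_equal(nrow(g), 4500)
  expect_lt(abs(var(g$y1) - sum(cfg$G[1, 1], cfg$V_dam[1], cfg$V_resid[1])) /
              var(g$y1), 0.1)
  vc <- anova_oracle_balanced(g$y1, g$sire_id, g$dam_id)
  # 3 Monte-Carlo SDs (~1.6 each) of the sire mean-square estimator
  expect_lt(abs(vc$V_sire - cfg$G[1, 1] / 4), 4.8)
})

test_that("CSV round-trip preserves the tables", {
  sim <- simulate_dataset(sim_config(n_sires = 5, seed = 23))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(as.data.frame(ph), as.data.frame(sim$phenotypes))
  expect_equal(as.data.frame(ped), as.data.frame(sim$pedigree))
  expect_error(read_phenotypes(file.path(dir, "nope.csv")), "nope.csv")
})
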