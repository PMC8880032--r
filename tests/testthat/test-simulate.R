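test_that("degenerate configuration gives constant values", {
  cfg <- diallel_sim_config(n_males = 2, n_females = 2, cross_density = 1,
                            trait_mean = 5, var_gca_male = 0,
                            var_gca_female = 0, var_sca = 0, var_env = 0,
                            var_gxe = 0, var_block = 0, var_residual = 0,
                            var_parent = 0, seed = 1)
  sim <- simulate_diallel_trial(cfg)
  expect_true(all(sim$phenotypes$value == 5))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- diallel_sim_config(seed = 123)
  s1 <- simulate_diallel_trial(cfg)
  s2 <- simulate_diallel_trial(cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$plan$crosses, s2$plan$crosses)
  expect_identical(s1$truth$gca, s2$truth$gca)
  s3 <- simulate_diallel_trial(diallel_sim_config(seed = 124))
  expect_false(identical(s1$phenotypes$value, s3$phenotypes$value))
})

test_that("stored truth reassembles the simulated records exactly", {
  cfg <- diallel_sim_config(n_males = 3, n_females = 3, cross_density = 1,
                            seed = 77)
  sim <- simulate_diallel_trial(cfg)
  ph <- sim$phenotypes
  tr <- sim$truth
  hy <- ph[ph$role == "hybrid", ]
  plan <- sim$plan
  fem <- plan$crosses$female_id[match(hy$genotype, plan$crosses$hybrid_id)]
  mal <- plan$crosses$male_id[match(hy$genotype, plan$crosses$hybrid_id)]
  env <- paste(hy$location, hy$year, sep = ":")
  systematic <- cfg$trait_mean + tr$env_effects[env] +
    tr$gca[fem] + tr$gca[mal] + tr$sca[hy$genotype] +
    tr$gxe_effects[cbind(hy$genotype, env)] +
    mapply(function(e, r, b) tr$block_effects[[paste(e, r, sep = ":")]][b],
           env, hy$replicate, hy$block)
  resid <- hy$value - systematic
  # residuals are exactly the N(0, var_residual) draws: their variance
  # is near the configured value and they are uncorrelated with truth
  expect_equal(length(resid), nrow(hy))
  expect_lt(abs(var(resid) - cfg$var_residual), 0.35 * cfg$var_residual)
})

test_that("plot variance decomposes into the configured components", {
  # law of total variance at 2,000 hybrid genotypes: plot variance of
  # hybrids ~ gca_f + gca_m + sca + env + gxe + block + residual
  cfg <- diallel_sim_config(n_males = 40, n_females = 50,
                            cross_density = 1, n_locations = 2,
                            n_years = 2, n_reps = 1,
                            var_gca_male = 0.25, var_gca_female = 0.25,
                            var_sca = 0.05, var_env = 0, var_gxe = 0.1,
                            var_block = 0.1, var_residual = 1,
                            include_parents = FALSE, seed = 31)
  sim <- simulate_diallel_trial(cfg)
  expected <- 0.25 + 0.25 + 0.05 + 0.1 + 0.1 + 1
  ph <- sim$phenotypes
  within_env <- tapply(ph$value, paste(ph$location, ph$year), var)
  expect_lt(abs(mean(within_env) - expected) / expected, 0.1)
})

test_that("disconnected or impossible plans are rejected", {
  expect_error(diallel_sim_config(cross_density = 0), "cross_density")
  expect_error(diallel_sim_config(var_sca = -1), "variances")
})

test_that("independent floral traits have near-zero sample correlation", {
  cfg <- floral_sim_config(traits = c("PM", "AL", "DH"),
                           target_correlation = diag(3) |>
                             (\(m) {dimnames(m) <- list(c("PM","AL","DH"),
                                                        c("PM","AL","DH")); m})(),
                           n_genotypes = 1000, seed = 5)
  ph <- simulate_floral_seedset(cfg)
  wide <- do.call(cbind, split(ph$value, ph$trait))
  cc <- cor(wide)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.1))
})

test_that("the target seed-set correlation structure is recovered", {
  cfg <- floral_sim_config(n_genotypes = 1000, seed = 8)
  ph <- simulate_floral_seedset(cfg)
  wide <- sapply(split(ph, ph$trait), function(d)
    d$value[order(d$genotype)])
  r <- cor(wide[, "SEEDSET"], wide[, "PM"])
  expect_lt(abs(r - 0.97), 0.03)
  r2 <- cor(wide[, "SEEDSET"], wide[, "VAE"])
  expect_lt(abs(r2 - 0.94), 0.05)  # VAE is clipped to the 1-9 scale
})

test_that("score traits never leave their bounds and rounding works", {
  cfg <- floral_sim_config(n_genotypes = 500, round_scores = TRUE,
                           seed = 9)
  ph <- simulate_floral_seedset(cfg)
  sc <- ph[ph$trait %in% c("VAE", "PSH"), "value"]
  expect_true(all(sc >= 1 & sc <= 9))
  expect_true(all(sc == round(sc)))
})

test_that("PSD repair fixes marginal indefiniteness and rejects worse", {
  R <- diag(3)
  tr3 <- c("PM", "AL", "DH")
  dimnames(R) <- list(tr3, tr3)
  R[1, 2] <- R[2, 1] <- 0.99
  R[1, 3] <- R[3, 1] <- 0.99
  R[2, 3] <- R[3, 2] <- 0.95  # slightly indefinite (min eig ~ -0.0035)
  ev <- eigen(R, only.values = TRUE)$values
  expect_lt(min(ev), 0)
  cfg <- floral_sim_config(traits = tr3, target_correlation = R,
                           n_genotypes = 50, seed = 2)
  expect_s3_class(cfg, "floral_sim_config")
  expect_silent(simulate_floral_seedset(cfg))
  R2 <- R
  R2[2, 3] <- R2[3, 2] <- -0.9  # grossly inconsistent triangle
  expect_error(floral_sim_config(traits = tr3, target_correlation = R2),
               "positive semidefinite")
})
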