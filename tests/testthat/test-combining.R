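test_that("griffing_oracle solves small tables by hand", {
  # additive 2x2 table: no interaction
  o <- griffing_oracle(matrix(c(10, 14, 12, 16), 2, 2))
  expect_equal(unname(o$gca_male), c(-2, 2))
  expect_equal(unname(o$gca_female), c(-1, 1))
  expect_true(all(abs(o$sca) < 1e-12))
  # one perturbed cell: |sca| = 1 everywhere with alternating signs
  o2 <- griffing_oracle(matrix(c(10, 14, 12, 12), 2, 2))
  expect_equal(abs(unname(o2$sca)), matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(sum(o2$sca), 0)
  expect_error(griffing_oracle(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("oracle identities hold for arbitrary tables", {
  set.seed(8)
  for (i in 1:25) {
    nr <- sample(2:6, 1)
    nc <- sample(2:6, 1)
    M <- matrix(stats::rnorm(nr * nc, 10), nr, nc)
    o <- griffing_oracle(M)
    expect_lt(abs(sum(o$gca_male)), 1e-10)
    expect_lt(abs(sum(o$gca_female)), 1e-10)
    expect_true(all(abs(rowSums(o$sca)) < 1e-10))
    expect_true(all(abs(colSums(o$sca)) < 1e-10))
    recon <- o$mu + outer(o$gca_male, o$gca_female, "+") + o$sca
    expect_equal(recon, M, tolerance = 1e-12)
  }
})

test_that("fixed-mode estimates equal the closed form on complete grids", {
  for (dims in list(c(3, 4), c(5, 5), c(8, 8))) {
    sim <- simulate_diallel_trial(diallel_sim_config(
      n_males = dims[1], n_females = dims[2], cross_density = 1,
      n_locations = 2, n_years = 1, n_reps = 2,
      var_gca_male = 0.3, var_gca_female = 0.3, var_sca = 0.1,
      var_env = 0.2, var_gxe = 0, var_block = 0, var_residual = 0.5,
      include_parents = FALSE, seed = 100 + dims[1]))
    ca <- fit_combining_ability(sim$phenotypes, sim$plan, "YLD",
                                mode = "fixed")
    o <- griffing_oracle(cross_cell_means(sim))
    g_or <- c(o$gca_male, o$gca_female)
    expect_lt(max(abs(ca$gca$effect - g_or[ca$gca$parent])), 1e-6)
    cr <- sim$plan$crosses
    s_fit <- stats::setNames(ca$sca$effect, ca$sca$hybrid)
    s_or <- vapply(seq_len(nrow(cr)), function(k)
      o$sca[cr$male_id[k], cr$female_id[k]], 0)
    expect_lt(max(abs(s_fit[cr$hybrid_id] - s_or)), 1e-6)
    # fitted cell means are reconstructed exactly: mu + gf + gm + s
    recon <- ca$engine$beta[1] + s_fit[cr$hybrid_id] +
      stats::setNames(ca$gca$effect, ca$gca$parent)[cr$female_id] +
      stats::setNames(ca$gca$effect, ca$gca$parent)[cr$male_id]
    cm <- cross_cell_means(sim)
    cm_vec <- vapply(seq_len(nrow(cr)), function(k)
      cm[cr$male_id[k], cr$female_id[k]], 0)
    expect_equal(unname(recon), cm_vec, tolerance = 1e-8)
  }
})

test_that("an additive, noise-free diallel is recovered exactly", {
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 4, n_females = 4, cross_density = 1, n_locations = 1,
    n_years = 1, n_reps = 2, var_gca_male = 0.4, var_gca_female = 0.4,
    var_sca = 0, var_env = 0, var_gxe = 0, var_block = 0,
    var_residual = 1e-12, include_parents = FALSE, seed = 5))
  ca <- fit_combining_ability(sim$phenotypes, sim$plan, "YLD",
                              mode = "fixed")
  expect_lt(max(abs(ca$sca$effect)), 1e-5)
  # estimated GCA equals the generating effects up to within-sex centering
  tru <- sim$truth$gca
  est <- stats::setNames(ca$gca$effect, ca$gca$parent)
  for (sx in c("male", "female")) {
    ids <- ca$gca$parent[ca$gca$role == sx]
    expect_lt(max(abs(est[ids] - (tru[ids] - mean(tru[ids])))), 1e-5)
  }
})

test_that("random-mode BLUPs shrink relative to fixed-mode estimates", {
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 4, n_females = 5, cross_density = 1, n_locations = 2,
    n_years = 1, n_reps = 2, var_gca_male = 0.2, var_gca_female = 0.2,
    var_sca = 0.05, var_env = 0.1, var_gxe = 0, var_block = 0,
    var_residual = 1, include_parents = FALSE, seed = 9))
  caf <- fit_combining_ability(sim$phenotypes, sim$plan, "YLD",
                               mode = "fixed")
  car <- fit_combining_ability(sim$phenotypes, sim$plan, "YLD",
                               mode = "random", gca_by_location = FALSE)
  # shrinkage in aggregate: BLUP effect vectors are shorter
  expect_lt(sqrt(sum(car$gca$effect^2)), sqrt(sum(caf$gca$effect^2)))
  expect_lt(sqrt(sum(car$sca$effect^2)), sqrt(sum(caf$sca$effect^2)) + 1e-9)
})

test_that("disconnected and underdetermined designs are caught", {
  # two crosses, four parents: fewer crosses than parents - 1
  parents <- data.frame(id = c("M1", "M2", "F1", "F2"),
                        sex_role = c("male", "male", "female", "female"))
  plan <- crossing_plan(parents, data.frame(
    female_id = c("F1", "F2"), male_id = c("M1", "M2")))
  tab <- data.frame(genotype = rep(plan$crosses$hybrid_id, each = 4),
                    role = "hybrid", location = "L1", year = 2001L,
                    replicate = rep(1:4, 2), block = 1L, trait = "YLD",
                    value = stats::rnorm(8))
  expect_error(fit_combining_ability(tab, plan, "YLD"), "rank-deficient")
  # two-component graph with enough crosses: fixed mode refuses,
  # random mode proceeds with a warning (BLUPs stay defined)
  parents2 <- data.frame(
    id = c("M1", "M2", "M3", "F1", "F2", "F3"),
    sex_role = c(rep("male", 3), rep("female", 3)))
  plan2 <- crossing_plan(parents2, data.frame(
    female_id = c("F1", "F2", "F1", "F2", "F3"),
    male_id = c("M1", "M1", "M2", "M2", "M3")))
  set.seed(2)
  tab2 <- data.frame(genotype = rep(plan2$crosses$hybrid_id, each = 4),
                     role = "hybrid", location = "L1", year = 2001L,
                     replicate = rep(1:4, 5), block = 1L, trait = "YLD",
                     value = stats::rnorm(20, 10))
  expect_error(fit_combining_ability(tab2, plan2, "YLD", mode = "fixed"),
               "disconnected")
  expect_warning(car <- fit_combining_ability(tab2, plan2, "YLD",
                                              mode = "random"),
                 "disconnected")
  expect_equal(nrow(car$gca), 6)
})

test_that("GCA/SCA variance ratio handles printed components and zeros", {
  expect_equal(round(gca_sca_ratio(c(sigma2_gca = 0.07,
                                     sigma2_sca = 0.011)), 2), 6.36)
  expect_equal(round(gca_sca_ratio(c(sigma2_gca = 0.08,
                                     sigma2_sca = 0.015)), 2), 5.33)
  expect_true(is.na(gca_sca_ratio(c(sigma2_gca = 0.19, sigma2_sca = 0))))
  expect_error(gca_sca_ratio(c(sigma2_gca = -1, sigma2_sca = 1)),
               "nonnegative")
  # ratio > 1 iff GCA variance dominates
  expect_gt(gca_sca_ratio(c(sigma2_gca = 0.3, sigma2_sca = 0.1)), 1)
  expect_lt(gca_sca_ratio(c(sigma2_gca = 0.1, sigma2_sca = 0.3)), 1)
})

test_that("random-mode parameter recovery works at trial scale", {
  # a short version of the full recovery study (the acceptance suite
  # runs 500 replicates): 30 partial diallels at the trial dimensions
  set.seed(202)
  seeds <- sample.int(1e6, 30)
  est <- t(vapply(seeds, function(s) {
    sim <- simulate_diallel_trial(diallel_sim_config(
      n_males = 7, n_females = 11, cross_density = 23 / 77,
      n_locations = 2, n_years = 2, n_reps = 2,
      var_gca_male = 0.25, var_gca_female = 0.25, var_sca = 0.05,
      var_env = 0, var_gxe = 0, var_block = 0, var_residual = 1,
      include_parents = FALSE, seed = s))
    ca <- fit_combining_ability(sim$phenotypes, sim$plan, "YLD",
                                mode = "random", gca_by_location = FALSE)
    c(gca = unname(ca$varcomps["sigma2_gca"]),
      sca = unname(ca$varcomps["sigma2_sca"]),
      e = unname(ca$varcomps["sigma2_e"]),
      r = cor(ca$gca$effect, sim$truth$gca[ca$gca$parent]))
  }, numeric(4)))
  expect_lt(abs(mean(est[, "e"]) - 1), 0.05)
  expect_lt(abs(mean(est[, "gca"]) - 0.25), 0.25 * 0.35)
  expect_gt(mean(est[, "r"]), 0.75)
})
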