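test_that("genotype-fixed fit with no random terms reduces to OLS means", {
  tab <- one_way_data(g = 5, r = 3, s2g = 2, s2e = 0.3, seed = 11)
  fit <- fit_reml(tab, model_spec("YLD", fixed = "genotype",
                                  random = character(0), scope = "yearly"))
  blues <- extract_blues(fit)
  means <- tapply(tab$value, tab$genotype, mean)
  expect_equal(blues$estimate, as.numeric(means[blues$genotype]),
               tolerance = 1e-10)
  # BLUE lies within the genotype's own plot range
  rng <- tapply(tab$value, tab$genotype, range)
  for (i in seq_len(nrow(blues))) {
    expect_gte(blues$estimate[i], rng[[blues$genotype[i]]][1])
    expect_lte(blues$estimate[i], rng[[blues$genotype[i]]][2])
  }
})

test_that("balanced one-way REML equals ANOVA method of moments", {
  for (seed in c(2, 3, 5)) {
    tab <- one_way_data(g = 12, r = 5, s2g = 1.5, s2e = 0.8, seed = seed)
    fit <- fit_reml(tab, model_spec("YLD", fixed = character(0),
                                    random = "genotype", scope = "yearly"))
    mom <- one_way_mom(tab)
    if (mom["s2g"] >= 0) {
      expect_equal(unname(fit$varcomps["genotype"]), unname(mom["s2g"]),
                   tolerance = 1e-6)
      expect_equal(unname(fit$varcomps["residual"]), unname(mom["s2e"]),
                   tolerance = 1e-6)
    }
  }
})

test_that("components and likelihood match an independent REML fit", {
  skip_if_not_installed("lme4")
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 4, n_females = 5, cross_density = 0.8, seed = 21))
  tab <- sim$phenotypes
  fit <- fit_reml(tab, spec_combined("YLD", "random"))
  env <- paste(tab$location, tab$year, sep = ":")
  blk <- paste(env, tab$replicate, tab$block, sep = ":")
  ge <- paste(tab$genotype, env, sep = ":")
  # use the same sum-to-zero fixed basis: the REML criterion depends on
  # the fixed-effects basis through log|X'V^-1 X|
  d <- cbind(tab, envf = factor(env), ge = ge, blk = blk)
  m <- suppressMessages(lme4::lmer(
    value ~ envf + (1 | genotype) + (1 | ge) + (1 | blk), data = d,
    contrasts = list(envf = "contr.sum"), REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$varcomps["genotype"]), unname(ref["genotype"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$varcomps["genotype:env"]), unname(ref["ge"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$varcomps["block"]), unname(ref["blk"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$varcomps["residual"]), unname(ref["Residual"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("restricted log-likelihood never decreases across EM iterations", {
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 3, n_females = 4, cross_density = 1, seed = 13))
  fit <- fit_reml(sim$phenotypes, spec_combined("YLD", "random"))
  tr <- fit$loglik_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) > -1e-6))
})

test_that("row permutation does not change the estimates", {
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 3, n_females = 3, cross_density = 1, seed = 17))
  tab <- sim$phenotypes
  f1 <- fit_reml(tab, spec_combined("YLD", "fixed"))
  set.seed(1)
  f2 <- fit_reml(tab[sample(nrow(tab)), ], spec_combined("YLD", "fixed"))
  b1 <- extract_blues(f1)
  b2 <- extract_blues(f2)
  expect_equal(b1$estimate, b2$estimate, tolerance = 1e-8)
  expect_equal(f1$varcomps, f2$varcomps, tolerance = 1e-7)
})

test_that("BLUEs with a missing plot solve the GLS normal equations", {
  tab <- one_way_data(g = 4, r = 3, s2g = 1, s2e = 0.4, seed = 23)
  tab$location <- ifelse(tab$replicate <= 2, "L1", "L2")
  tab <- tab[-2, ]  # drop one plot
  spec <- model_spec("YLD", fixed = c("genotype", "location"),
                     random = character(0), scope = "yearly")
  fit <- fit_reml(tab, spec)
  # direct dense normal-equation solve with the same coding
  gf <- factor(tab$genotype)
  lf <- factor(tab$location)
  X <- cbind(stats::model.matrix(~ 0 + gf),
             stats::model.matrix(~lf, contrasts.arg =
                                   list(lf = "contr.sum"))[, -1, drop = FALSE])
  beta <- qr.solve(X, tab$value)
  expect_equal(extract_blues(fit)$estimate,
               as.numeric(beta[seq_len(nlevels(gf))]), tolerance = 1e-8)
})

test_that("BLUP shrinkage matches the closed-form ridge factor", {
  tab <- one_way_data(g = 15, r = 4, s2g = 2, s2e = 1, seed = 31)
  fit <- fit_reml(tab, model_spec("YLD", fixed = character(0),
                                  random = "genotype", scope = "yearly"))
  s2g <- fit$varcomps["genotype"]
  s2e <- fit$varcomps["residual"]
  r <- 4
  shrink <- r * s2g / (r * s2g + s2e)
  centered <- tapply(tab$value, tab$genotype, mean) - mean(tab$value)
  blups <- extract_blups(fit)
  expect_equal(blups$blup, as.numeric(shrink * centered[blups$genotype]),
               tolerance = 1e-6)
  expect_lt(abs(mean(blups$blup)), 1e-8)
  # no-shrinkage and full-shrinkage limits of the same factor
  expect_true(all(abs(blups$blup) <= abs(centered[blups$genotype]) + 1e-12))
})

test_that("a zero genotypic variance pins the component and BLUPs at 0", {
  tab <- one_way_data(g = 10, r = 6, s2g = 0, s2e = 1, seed = 41)
  fit <- fit_reml(tab, model_spec("YLD", fixed = character(0),
                                  random = "genotype", scope = "yearly"))
  if (fit$varcomps["genotype"] == 0) {
    expect_true(fit$boundary["genotype"])
    expect_true(all(extract_blups(fit)$blup == 0))
  } else {
    # sampling may leave a small positive component; it must be tiny
    expect_lt(fit$varcomps["genotype"], 0.2)
  }
})

test_that("residual variance is recovered in a large simulated trial", {
  sim <- simulate_diallel_trial(diallel_sim_config(
    n_males = 20, n_females = 25, cross_density = 1, n_locations = 2,
    n_years = 2, n_reps = 2, var_gca_male = 0.25, var_gca_female = 0.25,
    var_sca = 0.05, var_env = 0.1, var_gxe = 0.05, var_block = 0.02,
    var_residual = 1, include_parents = FALSE, seed = 51))
  # 500 hybrid genotypes x 4 environments x 2 reps
  expect_equal(length(unique(sim$phenotypes$genotype)), 500)
  fit <- fit_reml(sim$phenotypes, spec_combined("YLD", "random"))
  expect_lt(abs(fit$varcomps["residual"] - 1), 0.1)
})

test_that("extractors refuse the wrong genotype role", {
  tab <- one_way_data(g = 5, r = 3, seed = 61)
  ffix <- fit_reml(tab, model_spec("YLD", fixed = "genotype",
                                   random = character(0), scope = "yearly"))
  fran <- fit_reml(tab, model_spec("YLD", fixed = character(0),
                                   random = "genotype", scope = "yearly"))
  expect_error(extract_blups(ffix), "genotype random")
  expect_error(extract_blues(fran), "genotype fixed")
  expect_error(model_spec("YLD", fixed = "genotype", random = "genotype"),
               "both fixed and random")
})

test_that("variance-component likelihood-ratio stars behave sanely", {
  tab <- one_way_data(g = 20, r = 4, s2g = 3, s2e = 0.5, seed = 71)
  fit <- fit_reml(tab, model_spec("YLD", fixed = character(0),
                                  random = "genotype", scope = "yearly"))
  tt <- test_varcomps(fit)
  expect_equal(tt$term, "genotype")
  expect_lt(tt$p_value, 0.001)
  expect_match(tt$stars, "\\*")
})
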