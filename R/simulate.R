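#' @title Synthetic diallel trials with known genetic truth
#' @description Generators that emulate the structure of a hybrid wheat
#'   partial-diallel yield trial (incomplete male x female factorial,
#'   multi-location multi-year alpha-lattice-style layout) and of a
#'   crossing-block experiment with correlated male floral traits and
#'   seed set. Every random effect drawn is stored, so downstream
#'   estimators can be tested against the generating truth.
#' @name synthetic-data
NULL

#' Configuration for a simulated diallel trial
#'
#' Defaults mirror the scale of a 7-male x 11-female spring bread wheat
#' diallel with 23 of 77 crosses realized, evaluated with the 18 parents
#' in 2 locations x 2 years x 2 replicates. Default variance components
#' are on the grain-yield scale (trait units t/ha, variances in
#' (t/ha)^2): per-parent GCA variance 0.07, SCA variance 0.011,
#' GCA-by-location variance 0.02 enters through \code{var_gxe}, plot
#' residual about 1. Parents' per-se genetic value is
#' \code{2 * gca + d} with \code{d ~ N(0, var_parent)}, so a purely
#' additive configuration makes the expected F1 equal the mid-parent
#' value.
#'
#' @param n_males,n_females number of male and female parents.
#' @param cross_density fraction of the male x female grid realized
#'   (in (0, 1]); the realized count is never below the
#'   \code{n_males + n_females - 1} crosses needed for estimability.
#' @param n_locations,n_years,n_reps layout dimensions.
#' @param trait trait name for the records (must be in the registry).
#' @param trait_mean grand mean, trait units.
#' @param var_gca_male,var_gca_female,var_sca,var_env,var_gxe,var_block,var_residual
#'   variance components (trait units squared, all >= 0). \code{var_env}
#'   is the environment (location x year) main-effect variance,
#'   \code{var_gxe} the genotype-by-environment interaction variance,
#'   \code{var_block} the incomplete-block variance.
#' @param include_parents also simulate the parents per se.
#' @param var_parent extra genetic variance of parent per-se values.
#' @param block_size target number of plots per incomplete block.
#' @param seed integer RNG seed; fixes every byte of the output.
#' @return a list of class \code{diallel_sim_config}.
#' @export
diallel_sim_config <- function(n_males = 7, n_females = 11,
                               cross_density = 23 / 77,
                               n_locations = 2, n_years = 2, n_reps = 2,
                               trait = "YLD", trait_mean = 4.2,
                               var_gca_male = 0.07, var_gca_female = 0.07,
                               var_sca = 0.011, var_env = 0.2,
                               var_gxe = 0.02, var_block = 0.05,
                               var_residual = 1.06,
                               include_parents = TRUE, var_parent = 0.16,
                               block_size = 10, seed = 1L) {
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              cross_density = cross_density,
              n_locations = as.integer(n_locations),
              n_years = as.integer(n_years), n_reps = as.integer(n_reps),
              trait = trait, trait_mean = trait_mean,
              var_gca_male = var_gca_male, var_gca_female = var_gca_female,
              var_sca = var_sca, var_env = var_env, var_gxe = var_gxe,
              var_block = var_block, var_residual = var_residual,
              include_parents = isTRUE(include_parents),
              var_parent = var_parent, block_size = as.integer(block_size),
              seed = as.integer(seed))
  vars <- cfg[grep("^var_", names(cfg))]
  if (any(unlist(vars) < 0)) stop("variances must be >= 0", call. = FALSE)
  if (cfg$cross_density <= 0 || cfg$cross_density > 1) {
    stop("cross_density must be in (0, 1]", call. = FALSE)
  }
  if (cfg$n_males < 1 || cfg$n_females < 1 || cfg$n_reps < 1 ||
      cfg$n_locations < 1 || cfg$n_years < 1) {
    stop("layout dimensions must be >= 1", call. = FALSE)
  }
  trait_registry(trait)
  structure(cfg, class = "diallel_sim_config")
}

# Sample a connected partial-diallel plan: every parent gets at least one
# cross, then the grid is filled at random up to the target count;
# resampled until the crossing graph is connected.
sample_plan <- function(n_males, n_females, cross_density, max_tries = 200) {
  males <- sprintf("M%02d", seq_len(n_males))
  females <- sprintf("F%02d", seq_len(n_females))
  grid <- expand.grid(female_id = females, male_id = males,
                      stringsAsFactors = FALSE)
  target <- max(round(cross_density * nrow(grid)),
                n_males + n_females - 1)
  target <- min(target, nrow(grid))
  parents <- data.frame(
    id = c(males, females),
    sex_role = c(rep("male", n_males), rep("female", n_females)),
    stringsAsFactors = FALSE
  )
  for (try in seq_len(max_tries)) {
    ord <- sample.int(nrow(grid))
    picked <- logical(nrow(grid))
    have_f <- character(0); have_m <- character(0)
    # first pass: cover every parent
    for (k in ord) {
      if (!(grid$female_id[k] %in% have_f) ||
          !(grid$male_id[k] %in% have_m)) {
        picked[k] <- TRUE
        have_f <- union(have_f, grid$female_id[k])
        have_m <- union(have_m, grid$male_id[k])
      }
      if (length(have_f) == n_females && length(have_m) == n_males) break
    }
    room <- target - sum(picked)
    if (room > 0) {
      free <- setdiff(ord, which(picked))
      picked[free[seq_len(min(room, length(free)))]] <- TRUE
    }
    plan <- crossing_plan(parents, grid[picked, , drop = FALSE])
    comp <- crossing_components(plan)
    if (length(unique(comp)) == 1L) return(plan)
  }
  stop("could not sample a connected crossing plan; increase cross_density",
       call. = FALSE)
}

#' Simulate a partial-diallel multi-environment trial
#'
#' Draws all effects from independent zero-mean normal distributions and
#' assembles plot values as
#' \code{mean + env + gca_f + gca_m + sca + gxe + block + residual} for
#' hybrids and \code{mean + env + 2 gca + d + gxe + block + residual}
#' for parents per se. Within each environment x replicate, genotypes
#' are laid out in incomplete blocks of roughly \code{block_size} plots.
#' Output is deterministic for a fixed seed.
#'
#' @param cfg a [diallel_sim_config()].
#' @param plan optional [crossing_plan()] to use instead of sampling one
#'   (its parent roster must split into males and females).
#' @return list with elements \code{phenotypes} (long table),
#'   \code{plan} (crossing plan) and \code{truth} (list of the drawn
#'   effects, plus the seed).
#' @export
#' @examples
#' sim <- simulate_diallel_trial(diallel_sim_config(
#'   n_males = 2, n_females = 3, cross_density = 1, seed = 7))
#' head(sim$phenotypes)
simulate_diallel_trial <- function(cfg = diallel_sim_config(), plan = NULL) {
  stopifnot(inherits(cfg, "diallel_sim_config"))
  set.seed(cfg$seed)
  if (is.null(plan)) {
    plan <- sample_plan(cfg$n_males, cfg$n_females, cfg$cross_density)
  }
  parents <- plan$parents$id
  crosses <- plan$crosses
  role <- stats::setNames(plan$parents$sex_role, parents)

  gca <- stats::setNames(
    stats::rnorm(length(parents)) *
      sqrt(ifelse(role == "male", cfg$var_gca_male, cfg$var_gca_female)),
    parents)
  sca <- stats::setNames(
    stats::rnorm(nrow(crosses), sd = sqrt(cfg$var_sca)), crosses$hybrid_id)
  parent_dev <- stats::setNames(
    stats::rnorm(length(parents), sd = sqrt(cfg$var_parent)), parents)

  envs <- expand.grid(location = sprintf("L%d", seq_len(cfg$n_locations)),
                      year = 2000L + seq_len(cfg$n_years),
                      stringsAsFactors = FALSE)
  env_id <- paste(envs$location, envs$year, sep = ":")
  env_eff <- stats::setNames(
    stats::rnorm(nrow(envs), sd = sqrt(cfg$var_env)), env_id)

  genos <- crosses$hybrid_id
  gvalue <- gca[crosses$female_id] + gca[crosses$male_id] +
    sca[crosses$hybrid_id]
  names(gvalue) <- genos
  grole <- rep("hybrid", length(genos))
  if (cfg$include_parents) {
    genos <- c(genos, parents)
    gvalue <- c(gvalue, 2 * gca + parent_dev)
    grole <- c(grole, rep("parent", length(parents)))
  }
  names(grole) <- genos

  gxe <- matrix(stats::rnorm(length(genos) * nrow(envs),
                             sd = sqrt(cfg$var_gxe)),
                length(genos), nrow(envs),
                dimnames = list(genos, env_id))

  n_blocks <- max(1L, ceiling(length(genos) / cfg$block_size))
  rows <- vector("list", nrow(envs) * cfg$n_reps)
  block_eff <- list()
  k <- 0L
  for (e in seq_len(nrow(envs))) {
    for (r in seq_len(cfg$n_reps)) {
      k <- k + 1L
      blk <- sample(rep_len(seq_len(n_blocks), length(genos)))
      be <- stats::rnorm(n_blocks, sd = sqrt(cfg$var_block))
      block_eff[[paste(env_id[e], r, sep = ":")]] <- be
      value <- cfg$trait_mean + env_eff[e] + gvalue + gxe[, e] +
        be[blk] + stats::rnorm(length(genos), sd = sqrt(cfg$var_residual))
      rows[[k]] <- data.frame(
        genotype = genos, role = grole[genos],
        location = envs$location[e], year = envs$year[e],
        replicate = r, block = blk, trait = cfg$trait,
        value = as.numeric(value), stringsAsFactors = FALSE)
    }
  }
  phen <- do.call(rbind, rows)
  rownames(phen) <- NULL
  truth <- list(gca = gca, sca = sca, parent_dev = parent_dev,
                env_effects = env_eff, gxe_effects = gxe,
                block_effects = block_eff,
                gca_mean = mean(gca), sca_mean = mean(sca),
                generator_seed = cfg$seed)
  list(phenotypes = validate_phenotypes(phen), plan = plan, truth = truth)
}

#' Default floral-trait correlation target
#'
#' Correlation structure among male floral, phenology and seed-set
#' traits observed in a two-year crossing-block experiment on 18 elite
#' spring bread wheat parents: seed set is tightly correlated with
#' pollen mass (0.97), visual anther extrusion (0.94), pollen shedding
#' (0.91) and grain yield per spike (0.98), while phenology traits are
#' nearly uncorrelated with seed set.
#'
#' @return symmetric 9 x 9 correlation matrix with unit diagonal.
#' @export
floral_correlation_target <- function() {
  tr <- c("DH", "PLH", "SPS", "GYS", "PM", "PSH", "VAE", "AL", "SEEDSET")
  R <- diag(9)
  dimnames(R) <- list(tr, tr)
  low <- list(
    PLH = c(DH = -0.47),
    SPS = c(DH = 0.11, PLH = 0.63),
    GYS = c(DH = 0.21, PLH = 0.15, SPS = 0.66),
    PM  = c(DH = 0.28, PLH = 0.25, SPS = 0.81, GYS = 0.94),
    PSH = c(DH = 0.35, PLH = 0.30, SPS = 0.87, GYS = 0.86, PM = 0.96),
    VAE = c(DH = 0.32, PLH = 0.25, SPS = 0.82, GYS = 0.90, PM = 0.95,
            PSH = 0.95),
    AL  = c(DH = 0.67, PLH = -0.14, SPS = 0.32, GYS = 0.48, PM = 0.55,
            PSH = 0.60, VAE = 0.55),
    SEEDSET = c(DH = 0.18, PLH = 0.29, SPS = 0.79, GYS = 0.98, PM = 0.97,
                PSH = 0.91, VAE = 0.94, AL = 0.46)
  )
  for (r in names(low)) {
    R[r, names(low[[r]])] <- low[[r]]
    R[names(low[[r]]), r] <- low[[r]]
  }
  R
}

#' Configuration for the correlated floral-trait generator
#'
#' @param traits trait names (subset of the registry).
#' @param target_correlation symmetric target correlation matrix with
#'   unit diagonal over \code{traits}. Marginally non-positive-definite
#'   matrices (smallest eigenvalue above \code{-repair_tol}) are
#'   repaired by flooring eigenvalues at zero and renormalizing to unit
#'   diagonal; anything worse is a configuration error.
#' @param means,sds per-trait genotype-level means and standard
#'   deviations (trait units).
#' @param n_genotypes,n_years panel size and number of year replicates.
#' @param noise_sd within-genotype year-to-year noise standard deviation
#'   applied to all traits (0 keeps the latent values).
#' @param round_scores round 1-9 score traits to whole scores after
#'   clipping.
#' @param repair_tol tolerance on the most negative eigenvalue that is
#'   still repaired rather than rejected.
#' @param seed integer RNG seed.
#' @return list of class \code{floral_sim_config}.
#' @export
floral_sim_config <- function(traits = colnames(floral_correlation_target()),
                              target_correlation = floral_correlation_target(),
                              means = c(DH = 104.38, PLH = 98.19, SPS = 19.61,
                                        GYS = 1.82, PM = 33.42, PSH = 7.65,
                                        VAE = 7.73, AL = 3.81,
                                        SEEDSET = 35.68),
                              sds = c(DH = 2.50, PLH = 3.26, SPS = 1.49,
                                      GYS = 0.73, PM = 4.62, PSH = 0.82,
                                      VAE = 1.02, AL = 0.79, SEEDSET = 4.39),
                              n_genotypes = 18, n_years = 1, noise_sd = 0,
                              round_scores = FALSE, repair_tol = 0.15,
                              seed = 1L) {
  trait_registry(traits)
  R <- as.matrix(target_correlation)[traits, traits, drop = FALSE]
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10) {
    stop("target correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -repair_tol) {
    stop("target correlation is not positive semidefinite beyond the ",
         "repair tolerance (min eigenvalue ", signif(min(ev), 3), ")",
         call. = FALSE)
  }
  structure(list(traits = traits, target_correlation = R,
                 means = means[traits], sds = sds[traits],
                 n_genotypes = as.integer(n_genotypes),
                 n_years = as.integer(n_years), noise_sd = noise_sd,
                 round_scores = isTRUE(round_scores),
                 repair_tol = repair_tol, seed = as.integer(seed)),
            class = "floral_sim_config")
}

# Repair a marginally indefinite correlation matrix: floor eigenvalues at
# zero, rebuild, renormalize to unit diagonal.
repair_psd <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(R)
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(R2)
}

#' Simulate correlated floral traits and seed set
#'
#' Genotype-level latent values are drawn from a multivariate normal
#' with the configured means, standard deviations and (repaired)
#' correlation target, via the Cholesky factor of the covariance.
#' Year observations add independent noise; 1-9 visual scores are
#' clipped to their bounds (which attenuates their correlations
#' slightly; the latent draw honours the target exactly).
#'
#' @param cfg a [floral_sim_config()].
#' @return long phenotype table (location \code{"CB"}, the crossing
#'   block; one row per genotype x year x trait).
#' @export
simulate_floral_seedset <- function(cfg = floral_sim_config()) {
  stopifnot(inherits(cfg, "floral_sim_config"))
  set.seed(cfg$seed)
  R <- repair_psd(cfg$target_correlation)
  S <- diag(cfg$sds) %*% R %*% diag(cfg$sds)
  # chol() needs strict PD; add a whisper of ridge if the repair floored
  # an eigenvalue at exactly zero.
  L <- tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-8 * max(diag(S)), nrow(S)))
  })
  n <- cfg$n_genotypes
  Zmat <- matrix(stats::rnorm(n * length(cfg$traits)), n)
  latent <- sweep(Zmat %*% L, 2, cfg$means, "+")
  colnames(latent) <- cfg$traits
  genos <- sprintf("G%03d", seq_len(n))
  reg <- trait_registry()
  rows <- vector("list", cfg$n_years)
  for (y in seq_len(cfg$n_years)) {
    obs <- latent
    if (cfg$noise_sd > 0) {
      obs <- obs + matrix(stats::rnorm(length(obs), sd = cfg$noise_sd),
                          nrow(obs))
    }
    for (tr in cfg$traits) {
      if (is_score_trait(tr, reg)) {
        i <- match(tr, reg$name)
        obs[, tr] <- pmin(pmax(obs[, tr], reg$scale_min[i]), reg$scale_max[i])
        if (cfg$round_scores) obs[, tr] <- round(obs[, tr])
      }
    }
    rows[[y]] <- data.frame(
      genotype = rep(genos, length(cfg$traits)),
      role = "parent", location = "CB", year = 2000L + y,
      replicate = 1L, block = 1L,
      trait = rep(cfg$traits, each = n),
      value = as.numeric(obs), stringsAsFactors = FALSE)
  }
  phen <- do.call(rbind, rows)
  rownames(phen) <- NULL
  validate_phenotypes(phen)
}
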