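# Shared fixture builders for the test suite. Everything is generated
# in code; no binary data.

# Balanced one-way layout: g genotypes x r replicates in one
# environment, genotype effects drawn N(0, s2g), residuals N(0, s2e).
one_way_data <- function(g = 10, r = 4, s2g = 1, s2e = 0.5, mu = 5,
                         seed = 1) {
  set.seed(seed)
  geno <- sprintf("G%02d", seq_len(g))
  eff <- rnorm(g, sd = sqrt(s2g))
  df <- expand.grid(genotype = geno, replicate = seq_len(r),
                    stringsAsFactors = FALSE)
  df$value <- mu + eff[match(df$genotype, geno)] +
    rnorm(nrow(df), sd = sqrt(s2e))
  df$role <- "parent"
  df$location <- "L1"
  df$year <- 2001L
  df$block <- 1L
  df$trait <- "YLD"
  validate_phenotypes(df[, c("genotype", "role", "location", "year",
                             "replicate", "block", "trait", "value")])
}

# ANOVA method-of-moments components for balanced one-way data.
one_way_mom <- function(tab) {
  a <- stats::anova(stats::lm(value ~ genotype, data = tab))
  r <- nrow(tab) / length(unique(tab$genotype))
  c(s2g = (a[1, 3] - a[2, 3]) / r, s2e = a[2, 3])
}

# Cell means (male x female matrix) of a complete-grid simulation.
cross_cell_means <- function(sim) {
  cr <- sim$plan$crosses
  cmn <- vapply(split(sim$phenotypes$value, sim$phenotypes$genotype),
                mean, 0)
  males <- sort(unique(cr$male_id))
  fems <- sort(unique(cr$female_id))
  M <- matrix(NA_real_, length(males), length(fems),
              dimnames = list(males, fems))
  for (k in seq_len(nrow(cr))) {
    M[cr$male_id[k], cr$female_id[k]] <- cmn[cr$hybrid_id[k]]
  }
  M
}

# Minimal valid crossing plan data frames.
tiny_plan <- function() {
  crossing_plan(
    parents = data.frame(id = c("A", "B"), sex_role = c("female", "male")),
    crosses = data.frame(female_id = "A", male_id = "B")
  )
}
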