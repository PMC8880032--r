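#' @title Mixed models for multi-environment trial data
#' @description User-facing REML fits of the trial models: genotype
#'   taken as fixed to obtain BLUEs (adjusted genotype means used for
#'   correlations and heterosis) or as random to obtain BLUPs and the
#'   genotypic variance components that feed heritability.
#' @name mixed-model
NULL

.fixed_factors <- c("genotype", "location", "year", "env", "replicate",
                    "block", "location:year")

#' Specify a trial mixed model
#'
#' Factors available: \code{genotype}, \code{location}, \code{year},
#' \code{env} (location x year), \code{replicate} (nested in
#' environment), \code{block} (nested in environment and replicate) and
#' interactions written with \code{":"} such as \code{genotype:env} or
#' \code{genotype:year}. A factor may appear as fixed or random, not
#' both.
#'
#' @param response trait name (must be in the registry).
#' @param fixed character vector of fixed terms.
#' @param random character vector of random terms.
#' @param scope free-text label, "yearly" or "combined".
#' @return object of class \code{model_spec}.
#' @export
#' @examples
#' model_spec("YLD", fixed = c("genotype", "location"), random = "block")
model_spec <- function(response, fixed = "genotype", random = "block",
                       scope = "combined") {
  trait_registry(response)
  both <- intersect(fixed, random)
  if (length(both)) {
    stop("term(s) listed as both fixed and random: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, random = random,
                 scope = scope), class = "model_spec")
}

#' Canned model for the combined (across environments) analysis
#'
#' Locations, years and their interaction are fixed; genotype (when
#' random), genotype-by-environment and incomplete blocks are random.
#'
#' @param trait trait name.
#' @param genotype "fixed" (for BLUEs) or "random" (for BLUPs and
#'   genotypic variance components).
#' @param gxe include the genotype-by-environment random term.
#' @param blocks include the random block term.
#' @return a [model_spec()].
#' @export
spec_combined <- function(trait, genotype = c("fixed", "random"),
                          gxe = TRUE, blocks = TRUE) {
  genotype <- match.arg(genotype)
  # one env factor spans the location, year and location:year columns
  fixed <- c(if (genotype == "fixed") "genotype", "env")
  random <- c(if (genotype == "random") "genotype",
              if (gxe) "genotype:env", if (blocks) "block")
  model_spec(trait, fixed, random, scope = "combined")
}

#' Canned model for a single-environment (yearly) analysis
#'
#' Genotype fixed or random; incomplete blocks random, following the
#' yearly trial model (one location-year at a time).
#'
#' @inheritParams spec_combined
#' @return a [model_spec()].
#' @export
spec_single_env <- function(trait, genotype = c("fixed", "random"),
                            blocks = TRUE) {
  genotype <- match.arg(genotype)
  model_spec(trait,
             fixed = if (genotype == "fixed") "genotype" else character(0),
             random = c(if (genotype == "random") "genotype",
                        if (blocks) "block"),
             scope = "yearly")
}

# Resolve a model term to a factor on the table rows. Nesting rules:
# replicate is unique within an environment, block within an
# environment x replicate.
term_factor <- function(term, tab) {
  parts <- unique(unlist(strsplit(term, ":", fixed = TRUE)))
  cols <- unique(unlist(lapply(parts, function(pt) {
    switch(pt,
      genotype = "genotype",
      location = "location",
      year = "year",
      env = c("location", "year"),
      replicate = c("location", "year", "replicate"),
      block = c("location", "year", "replicate", "block"),
      stop("unknown model term part: ", pt, call. = FALSE))
  })))
  f <- interaction(tab[cols], drop = TRUE, sep = ":", lex.order = TRUE)
  droplevels(f)
}

# Sum-contrast design columns (no intercept column) for nuisance fixed
# terms, so that genotype cell-mean coefficients average over them.
nuisance_columns <- function(terms, tab) {
  if (!length(terms)) return(NULL)
  blocks <- lapply(terms, function(tm) {
    f <- term_factor(tm, tab)
    if (nlevels(f) < 2) return(NULL)
    mm <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))
    mm <- mm[, -1, drop = FALSE]
    colnames(mm) <- paste0(tm, seq_len(ncol(mm)))
    mm
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) NULL else do.call(cbind, blocks)
}

#' Fit a trial mixed model by REML
#'
#' Builds the design matrices implied by a [model_spec()] and fits the
#' model with [reml_engine()]. When genotype is fixed it is coded as
#' cell means with sum-to-zero contrasts on the nuisance factors, so
#' each genotype coefficient is its adjusted mean (BLUE) averaged over
#' the other fixed factors.
#'
#' @param tab phenotype table (long format).
#' @param spec a [model_spec()].
#' @param ... passed to [reml_engine()] (e.g. \code{max_iter}).
#' @return object of class \code{reml_fit} with components
#'   \code{varcomps} (named vector incl. \code{residual}),
#'   \code{blues}/\code{blups} data frames, \code{loglik},
#'   \code{converged}, \code{n_iter}, \code{n_obs},
#'   \code{edf_residual}, plus the design internals used by
#'   [heterosis_significance()].
#' @export
fit_reml <- function(tab, spec, ...) {
  stopifnot(inherits(spec, "model_spec"))
  tab <- tab[tab$trait == spec$response & is.finite(tab$value), ,
             drop = FALSE]
  if (!nrow(tab)) stop("no observations for trait ", spec$response,
                       call. = FALSE)
  if (length(unique(tab$genotype)) < 2) {
    stop("need >= 2 genotypes with data", call. = FALSE)
  }
  y <- tab$value
  geno_fixed <- "genotype" %in% spec$fixed
  geno_random <- "genotype" %in% spec$random

  gf <- factor(tab$genotype)
  gf <- droplevels(gf)
  if (geno_fixed) {
    Xg <- stats::model.matrix(~ 0 + gf)
    colnames(Xg) <- levels(gf)
  } else {
    Xg <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
  }
  nuis <- nuisance_columns(setdiff(spec$fixed, "genotype"), tab)
  X <- if (is.null(nuis)) Xg else cbind(Xg, nuis)

  Z_list <- list()
  for (tm in spec$random) {
    f <- term_factor(tm, tab)
    if (nlevels(f) < 2) {
      warning("random term '", tm, "' has < 2 levels; dropped")
      next
    }
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    Z_list[[tm]] <- Z
  }

  eng <- reml_engine(y, X, Z_list, ...)
  if (length(eng$dropped_fixed)) {
    warning("aliased fixed-effect column(s) dropped: ",
            paste(eng$dropped_fixed, collapse = ", "))
  }

  glev <- levels(gf)
  blues <- blups <- NULL
  if (geno_fixed) {
    keep <- intersect(glev, names(eng$beta))
    blues <- data.frame(genotype = keep,
                        estimate = unname(eng$beta[keep]),
                        se = unname(eng$se_beta[keep]),
                        stringsAsFactors = FALSE)
    blues <- blues[order(blues$genotype), , drop = FALSE]
    rownames(blues) <- NULL
  }
  if (geno_random) {
    u <- eng$u[["genotype"]]
    pev <- eng$pev[["genotype"]]
    blups <- data.frame(genotype = names(u), blup = unname(u),
                        pev = unname(pev), se = sqrt(unname(pev)),
                        stringsAsFactors = FALSE)
    blups <- blups[order(blups$genotype), , drop = FALSE]
    rownames(blups) <- NULL
  }

  ne <- length(unique(paste(tab$location, tab$year)))
  nr <- max(tab$replicate)
  structure(list(
    varcomps = eng$sigma2, blues = blues, blups = blups,
    loglik = eng$loglik, loglik_trace = eng$loglik_trace,
    converged = eng$converged, n_iter = eng$n_iter,
    n_obs = eng$n, edf_residual = eng$edf_residual,
    boundary = eng$boundary, spec = spec,
    genotype_role = if (geno_fixed) "fixed" else
      if (geno_random) "random" else "none",
    n_environments = ne, n_replicates = nr,
    engine = eng, data = tab
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML fit:", x$spec$response, "(", x$spec$scope, "scope; genotype",
      x$genotype_role, ")\n")
  cat("  n =", x$n_obs, "; restricted logLik =",
      format(x$loglik, digits = digits + 2),
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  variance components:\n")
  vc <- round(x$varcomps, digits)
  for (i in seq_along(vc)) {
    cat(sprintf("    %-18s %s%s\n", names(vc)[i], format(vc[i]),
                if (isTRUE(x$boundary[names(vc)[i]])) " (boundary)" else ""))
  }
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$blues)) {
    cat("  BLUEs: ", nrow(object$blues), " genotypes, range [",
        format(min(object$blues$estimate), digits = 5), ", ",
        format(max(object$blues$estimate), digits = 5), "]\n", sep = "")
  }
  if (!is.null(object$blups)) {
    cat("  BLUPs: ", nrow(object$blups), " genotypes, mean ",
        format(mean(object$blups$blup), digits = 3), "\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.reml_fit <- function(object, ...) object$engine$beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomps) + object$engine$p,
            class = "logLik")
}

#' @export
fitted.reml_fit <- function(object, ...) object$engine$fitted

#' @export
residuals.reml_fit <- function(object, ...) {
  object$data$value - object$engine$fitted
}

#' Genotype BLUEs from a fixed-genotype fit
#'
#' @param fit a [fit_reml()] result with genotype fixed.
#' @return data frame \code{genotype}, \code{estimate}, \code{se},
#'   ordered by genotype id.
#' @export
extract_blues <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$genotype_role != "fixed") {
    stop("extract_blues() needs a fit with genotype fixed; this fit has ",
         "genotype ", fit$genotype_role, call. = FALSE)
  }
  fit$blues
}

#' Genotype BLUPs from a random-genotype fit
#'
#' @param fit a [fit_reml()] result with genotype random.
#' @return data frame \code{genotype}, \code{blup}, \code{pev},
#'   \code{se}, ordered by genotype id.
#' @export
extract_blups <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$genotype_role != "random") {
    stop("extract_blups() needs a fit with genotype random; this fit has ",
         "genotype ", fit$genotype_role, call. = FALSE)
  }
  fit$blups
}

#' Likelihood-ratio significance of a fit's variance components
#'
#' @param fit a [fit_reml()] result.
#' @return data frame from [varcomp_tests()].
#' @export
test_varcomps <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  eng <- fit$engine
  spec <- fit$spec
  tab <- fit$data
  geno_fixed <- fit$genotype_role == "fixed"
  gf <- droplevels(factor(tab$genotype))
  if (geno_fixed) {
    X <- stats::model.matrix(~ 0 + gf)
    colnames(X) <- levels(gf)
  } else {
    X <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
  }
  nuis <- nuisance_columns(setdiff(spec$fixed, "genotype"), tab)
  if (!is.null(nuis)) X <- cbind(X, nuis)
  Z_list <- list()
  for (tm in spec$random) {
    f <- term_factor(tm, tab)
    if (nlevels(f) < 2) next
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    Z_list[[tm]] <- Z
  }
  varcomp_tests(tab$value, X, Z_list, fit = eng)
}
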