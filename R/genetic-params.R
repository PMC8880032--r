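#' @title Heritability, LSD, genotypic CV and trait correlations
#' @description Genetic-parameter summaries computed from REML variance
#'   components and genotype BLUEs: broad- and narrow-sense
#'   heritability on an entry-mean basis, the least significant
#'   difference, the genotypic coefficient of variation, and Pearson
#'   correlation matrices between traits.
#' @name genetic-params
NULL

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{g \times e}/n_e +
#'   \sigma^2_e / (n_e n_r))}
#' where \eqn{n_e} is the number of environments and \eqn{n_r} the
#' number of replicates per environment.
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param sigma2_gxe genotype-by-environment interaction variance.
#' @param sigma2_e residual (plot error) variance.
#' @param ne,nr number of environments and replicates (>= 1).
#' @return heritability in [0, 1].
#' @export
#' @examples
#' broad_sense_h2(21.31, 14.43, 4.84, ne = 2, nr = 2)  # ~0.717
broad_sense_h2 <- function(sigma2_g, sigma2_gxe = 0, sigma2_e = 0,
                           ne = 1, nr = 1) {
  if (ne < 1 || nr < 1) stop("ne and nr must be >= 1", call. = FALSE)
  if (any(c(sigma2_g, sigma2_gxe, sigma2_e) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  denom <- sigma2_g + sigma2_gxe / ne + sigma2_e / (ne * nr)
  if (denom == 0) return(0)
  sigma2_g / denom
}

#' Narrow-sense heritability
#'
#' Computed on the hybrid-analysis variance components. The default
#' \code{variant = "standard"} uses the multi-environment entry-mean
#' formula and therefore coincides with [broad_sense_h2()] applied to
#' the same components (the components themselves decide how much of
#' the genetic variance is additive); the result carries an attribute
#' \code{interpretation} recording this. \code{variant = "as-printed"}
#' reproduces a formula sometimes seen in print that double-counts the
#' genotypic variance, \eqn{\sigma^2_g / (2\sigma^2_g +
#' \sigma^2_e/n_r)}; it is provided for comparison only.
#'
#' @inheritParams broad_sense_h2
#' @param variant "standard" or "as-printed".
#' @return heritability in [0, 1] with attribute \code{interpretation}.
#' @export
narrow_sense_h2 <- function(sigma2_g, sigma2_gxe = 0, sigma2_e = 0,
                            ne = 1, nr = 1,
                            variant = c("standard", "as-printed")) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    out <- broad_sense_h2(sigma2_g, sigma2_gxe, sigma2_e, ne, nr)
    attr(out, "interpretation") <-
      "entry-mean formula on hybrid-analysis components (equals H2 form)"
  } else {
    if (nr < 1) stop("nr must be >= 1", call. = FALSE)
    if (any(c(sigma2_g, sigma2_e) < 0)) {
      stop("variance components must be >= 0", call. = FALSE)
    }
    denom <- 2 * sigma2_g + sigma2_e / nr
    out <- if (denom == 0) 0 else sigma2_g / denom
    attr(out, "interpretation") <- "as-printed (duplicated sigma2_g)"
  }
  out
}

#' Least significant difference
#'
#' \eqn{LSD_\alpha = t_{1-\alpha/2, edf} \sqrt{2 \sigma^2_e / n_r}}.
#'
#' @param sigma2_e residual variance (>= 0).
#' @param nr number of replicates the compared means are based on.
#' @param edf residual degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @return nonnegative LSD in trait units.
#' @export
lsd <- function(sigma2_e, nr, edf, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (edf < 1) stop("edf must be >= 1", call. = FALSE)
  if (sigma2_e < 0) stop("sigma2_e must be >= 0", call. = FALSE)
  stats::qt(1 - alpha / 2, df = edf) * sqrt(2 * sigma2_e / nr)
}

#' Genotypic coefficient of variation
#'
#' \eqn{GCV = 100 \sqrt{\sigma^2_g} / \bar{x}}, in percent.
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param mean trait mean (> 0).
#' @return percent.
#' @export
gcv <- function(sigma2_g, mean) {
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (sigma2_g < 0) stop("sigma2_g must be >= 0", call. = FALSE)
  100 * sqrt(sigma2_g) / mean
}

#' Pearson correlation matrix between traits
#'
#' Correlations between per-genotype trait values (typically BLUEs),
#' with two-sided t-test p-values and pairwise-complete observations.
#' Constant traits yield NA with a warning.
#'
#' @param blues either a long data frame with columns \code{genotype},
#'   \code{trait}, \code{estimate}, or a wide data frame/matrix with
#'   genotypes in rows and traits in columns.
#' @return object of class \code{trait_correlations}: list with
#'   \code{traits}, \code{r}, \code{p}, \code{n} matrices.
#' @export
correlation_matrix <- function(blues) {
  if (is.data.frame(blues) &&
      all(c("genotype", "trait", "estimate") %in% names(blues))) {
    wide <- stats::reshape(
      blues[, c("genotype", "trait", "estimate")],
      idvar = "genotype", timevar = "trait", direction = "wide")
    rownames(wide) <- wide$genotype
    wide$genotype <- NULL
    colnames(wide) <- sub("^estimate\\.", "", colnames(wide))
    M <- as.matrix(wide)
  } else {
    M <- as.matrix(blues)
  }
  traits <- colnames(M)
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  diag(p) <- 0
  diag(nmat) <- colSums(is.finite(M))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j >= i) next
      ok <- is.finite(M[, i]) & is.finite(M[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        warning("fewer than 3 complete pairs for ", traits[i], " x ",
                traits[j])
        next
      }
      if (stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) {
        warning("constant trait in pair ", traits[i], " x ", traits[j],
                "; correlation undefined")
        next
      }
      ct <- stats::cor.test(M[ok, i], M[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(traits = traits, r = r, p = p, n = nmat),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("Pearson correlations (", length(x$traits), " traits)\n", sep = "")
  out <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  for (i in seq_len(nrow(x$r))) {
    for (j in seq_len(ncol(x$r))) {
      if (i == j || !is.finite(x$r[i, j])) next
      out[i, j] <- paste0(format(round(x$r[i, j], digits), nsmall = digits),
                          " ", significance_stars(x$p[i, j]))
    }
  }
  print(out[-1, -ncol(out), drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Genetic-parameter summary for one trait
#'
#' Combines a fixed-genotype fit (for the BLUE min/max/mean and LSD)
#' and a random-genotype fit (for the variance components and
#' heritability) into one summary row per trait.
#'
#' @param fit_fixed [fit_reml()] result with genotype fixed.
#' @param fit_random [fit_reml()] result with genotype random on the
#'   same data.
#' @param alpha LSD significance level.
#' @return one-row data frame: trait, min, max, mean, lsd_05, sigma2_g,
#'   sigma2_gxe, sigma2_e, H2, h2, gcv_percent, ne, nr.
#' @export
genetic_summary <- function(fit_fixed, fit_random, alpha = 0.05) {
  stopifnot(inherits(fit_fixed, "reml_fit"), inherits(fit_random, "reml_fit"))
  blues <- extract_blues(fit_fixed)
  vc <- fit_random$varcomps
  s2g <- unname(vc["genotype"])
  gxe_name <- grep("^genotype:", names(vc), value = TRUE)
  s2gxe <- if (length(gxe_name)) unname(vc[gxe_name[1]]) else 0
  s2e <- unname(vc["residual"])
  ne <- fit_random$n_environments
  nr <- fit_random$n_replicates
  H2 <- broad_sense_h2(s2g, s2gxe, s2e, ne, nr)
  h2 <- as.numeric(narrow_sense_h2(s2g, s2gxe, s2e, ne, nr))
  mn <- mean(blues$estimate)
  data.frame(
    trait = fit_fixed$spec$response,
    min = min(blues$estimate), max = max(blues$estimate), mean = mn,
    lsd_05 = lsd(s2e, nr * ne, fit_fixed$edf_residual, alpha),
    sigma2_g = s2g, sigma2_gxe = s2gxe, sigma2_e = s2e,
    H2 = H2, h2 = h2,
    gcv_percent = if (mn > 0) gcv(s2g, mn) else NA_real_,
    ne = ne, nr = nr, stringsAsFactors = FALSE
  )
}
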