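#' @title General and specific combining ability for a partial diallel
#' @description GCA/SCA analysis of the realized crosses of an
#'   incomplete male x female factorial, following the model
#'   \code{y_ijk = mu + g_i + g_j + s_ij + e_ijk} with environments
#'   (location x year) acting as replications. Because the realized
#'   design has neither selfs nor reciprocals, the model is fitted as a
#'   North-Carolina-II-style linear model on the realized crosses; the
#'   complete-grid closed form is kept as [griffing_oracle()] for
#'   verification.
#' @name combining-ability
NULL

# Sum-to-zero basis for parent effects, separately within males and
# within females (the Griffing/NCII convention). A single all-parent
# constraint leaves a male-vs-female shift unidentified on incomplete
# factorials without selfs.
parent_basis <- function(plan) {
  males <- plan$parents$id[plan$parents$sex_role == "male"]
  females <- plan$parents$id[plan$parents$sex_role == "female"]
  np <- length(males) + length(females)
  K <- matrix(0, np, np - 2,
              dimnames = list(c(males, females), NULL))
  if (length(males) > 1) {
    K[seq_along(males), seq_len(length(males) - 1)] <-
      stats::contr.sum(length(males))
  }
  if (length(females) > 1) {
    K[length(males) + seq_along(females),
      length(males) - 1 + seq_len(length(females) - 1)] <-
      stats::contr.sum(length(females))
  }
  K
}

#' Fit the combining-ability model for the realized crosses
#'
#' Uses hybrid plot records only (parents per se are excluded). In
#' \code{mode = "random"}, GCA and SCA are random effects estimated by
#' REML: one shared GCA variance for all parents (matching the single
#' printed GCA-parent component; set \code{separate_gca = TRUE} to
#' split male and female GCA variances), an SCA variance, an optional
#' GCA-by-location interaction variance, and plot residual.
#' Environments enter as fixed replication effects. Effects are BLUPs
#' with prediction-error-variance z-tests. In \code{mode = "fixed"},
#' effects are constrained least-squares estimates (sum-to-zero within
#' males and within females) with SCA as residual cross-mean
#' deviations and t-tests.
#'
#' @param tab phenotype table.
#' @param plan [crossing_plan()]; fixed mode requires a connected
#'   crossing graph (see [validate_design()]), random mode only warns
#'   since BLUPs remain defined on disconnected designs.
#' @param trait trait to analyze.
#' @param mode "random" or "fixed".
#' @param gca_by_location include the GCA x location random component
#'   (random mode, needs >= 2 locations).
#' @param separate_gca estimate male and female GCA variances
#'   separately (random mode).
#' @param ... passed to [reml_engine()].
#' @return object of class \code{diallel_ca}: list with \code{gca} and
#'   \code{sca} effect tables, \code{varcomps}, \code{ratio_gca_sca},
#'   \code{H2}, \code{mode}, \code{trait}, fit internals.
#' @export
fit_combining_ability <- function(tab, plan, trait,
                                  mode = c("random", "fixed"),
                                  gca_by_location = TRUE,
                                  separate_gca = FALSE, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "crossing_plan"))
  tab <- tab[tab$trait == trait & tab$genotype %in% plan$crosses$hybrid_id, ,
             drop = FALSE]
  if (!nrow(tab)) stop("no hybrid records for trait ", trait, call. = FALSE)
  if (nrow(plan$crosses) < nrow(plan$parents) - 1) {
    stop("fewer crosses than parents - 1: rank-deficient GCA structure",
         call. = FALSE)
  }
  rep_check <- validate_design(tab, plan)
  if (!rep_check$gca_estimable) {
    if (mode == "fixed") {
      stop("crossing design is disconnected or has parents without ",
           "crosses; fixed-mode GCA contrasts are not estimable",
           call. = FALSE)
    }
    warning("crossing design is disconnected (", rep_check$n_components,
            " components); GCA contrasts across components are related ",
            "only through shrinkage toward zero", call. = FALSE)
  }
  ids <- plan$parents$id
  cross_of <- match(tab$genotype, plan$crosses$hybrid_id)
  fem <- plan$crosses$female_id[cross_of]
  mal <- plan$crosses$male_id[cross_of]
  env <- factor(paste(tab$location, tab$year, sep = ":"))
  loc <- factor(tab$location)
  crossf <- factor(tab$genotype, levels = plan$crosses$hybrid_id)
  crossf <- droplevels(crossf)
  y <- tab$value
  n <- length(y)

  # shared parent incidence at observation level
  Zg <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  Zg[cbind(seq_len(n), match(fem, ids))] <- 1
  Zg[cbind(seq_len(n), match(mal, ids))] <- 1

  env_cols <- if (nlevels(env) > 1) {
    mm <- stats::model.matrix(~env, contrasts.arg = list(env = "contr.sum"))
    mm <- mm[, -1, drop = FALSE]
    colnames(mm) <- paste0("env", seq_len(ncol(mm)))
    mm
  } else NULL
  X <- cbind(`(Intercept)` = rep(1, n), env_cols)

  ne <- nlevels(env)
  nl <- nlevels(loc)
  nr <- max(tab$replicate)

  if (mode == "random") {
    Z_list <- list()
    if (separate_gca) {
      m_ids <- ids[plan$parents$sex_role == "male"]
      f_ids <- ids[plan$parents$sex_role == "female"]
      Z_list$gca_male <- Zg[, m_ids, drop = FALSE]
      Z_list$gca_female <- Zg[, f_ids, drop = FALSE]
    } else {
      Z_list$gca <- Zg
    }
    Zs <- stats::model.matrix(~ 0 + crossf)
    colnames(Zs) <- levels(crossf)
    Z_list$sca <- Zs
    if (gca_by_location && nl > 1) {
      # columns grouped by location, named parent:location
      Zgl <- matrix(0, n, length(ids) * nl, dimnames = list(NULL,
        as.vector(vapply(levels(loc), function(l)
          paste(ids, l, sep = ":"), character(length(ids))))))
      for (l in seq_len(nl)) {
        sel <- loc == levels(loc)[l]
        Zgl[sel, (l - 1) * length(ids) + seq_along(ids)] <- Zg[sel, ]
      }
      Z_list$gca_location <- Zgl
    }
    eng <- reml_engine(y, X, Z_list, ...)
    if (separate_gca) {
      gca_u <- c(eng$u$gca_male, eng$u$gca_female)[ids]
      gca_pev <- c(eng$pev$gca_male, eng$pev$gca_female)[ids]
      s2gca <- mean(eng$sigma2[c("gca_male", "gca_female")])
    } else {
      gca_u <- eng$u$gca[ids]
      gca_pev <- eng$pev$gca[ids]
      s2gca <- unname(eng$sigma2["gca"])
    }
    gca_se <- sqrt(gca_pev)
    gca_p <- ifelse(gca_se > 0, 2 * stats::pnorm(-abs(gca_u) / gca_se), 1)
    sca_u <- eng$u$sca[levels(crossf)]
    sca_pev <- eng$pev$sca[levels(crossf)]
    sca_se <- sqrt(sca_pev)
    sca_p <- ifelse(sca_se > 0, 2 * stats::pnorm(-abs(sca_u) / sca_se), 1)
    s2sca <- unname(eng$sigma2["sca"])
    s2gl <- if ("gca_location" %in% names(eng$sigma2))
      unname(eng$sigma2["gca_location"]) else 0
    s2e <- unname(eng$sigma2["residual"])
  } else {
    K <- parent_basis(plan)
    X_add <- cbind(X, Zg %*% K)
    fit_add <- stats::lm.fit(X_add, y)
    # saturated model for the error variance: cross cell means + env
    X_sat <- cbind(stats::model.matrix(~ 0 + crossf), env_cols)
    fit_sat <- stats::lm.fit(X_sat, y)
    df_sat <- n - fit_sat$rank
    s2e <- sum(fit_sat$residuals^2) / df_sat
    XtXi <- chol2inv(chol(crossprod(X_add)))
    alpha_ix <- ncol(X) + seq_len(ncol(K))
    gvec <- drop(K %*% fit_add$coefficients[alpha_ix])
    names(gvec) <- rownames(K)
    cov_alpha <- s2e * XtXi[alpha_ix, alpha_ix, drop = FALSE]
    cov_g <- K %*% cov_alpha %*% t(K)
    gca_u <- gvec[ids]
    gca_se <- sqrt(pmax(diag(cov_g)[ids], 0))
    gca_p <- ifelse(gca_se > 0,
                    2 * stats::pt(-abs(gca_u) / gca_se, df_sat), 1)
    # SCA: residual cross means of the additive fit, as explicit linear
    # functions of y so their SEs are exact
    H <- X_add %*% XtXi %*% t(X_add)
    Agg <- stats::model.matrix(~ 0 + crossf)
    Agg <- t(Agg) / colSums(Agg)
    Ls <- Agg %*% (diag(n) - H)
    sca_u <- drop(Ls %*% y)
    names(sca_u) <- levels(crossf)
    sca_se <- sqrt(pmax(diag(Ls %*% t(Ls)) * s2e, 0))
    sca_p <- ifelse(sca_se > 0,
                    2 * stats::pt(-abs(sca_u) / sca_se, df_sat), 1)
    sca_pev <- sca_se^2
    gca_pev <- gca_se^2
    # method-of-moments style components are not defined for the fixed
    # mode; report empirical variances of the effect estimates
    s2gca <- stats::var(gca_u)
    s2sca <- stats::var(sca_u)
    s2gl <- NA_real_
    eng <- list(beta = fit_add$coefficients, fitted = drop(X_add %*%
      ifelse(is.na(fit_add$coefficients), 0, fit_add$coefficients)),
      n = n, p = fit_add$rank, edf_residual = df_sat)
  }

  role <- stats::setNames(plan$parents$sex_role, ids)
  gca_tab <- data.frame(parent = ids, role = unname(role[ids]),
                        effect = unname(gca_u), se = unname(gca_se),
                        p_value = unname(gca_p),
                        stars = significance_stars(gca_p),
                        stringsAsFactors = FALSE)
  cr <- plan$crosses[match(levels(crossf), plan$crosses$hybrid_id), ]
  sca_tab <- data.frame(hybrid = cr$hybrid_id, female = cr$female_id,
                        male = cr$male_id, effect = unname(sca_u),
                        se = unname(sca_se), p_value = unname(sca_p),
                        stars = significance_stars(sca_p),
                        stringsAsFactors = FALSE)
  varcomps <- c(sigma2_gca = s2gca, sigma2_sca = s2sca,
                sigma2_gca_location = s2gl, sigma2_e = s2e)
  s2G <- 2 * s2gca + s2sca
  H2 <- if (mode == "random" && s2G + s2e > 0) {
    gxe_part <- if (is.na(s2gl)) 0 else 2 * s2gl / max(nl, 1)
    s2G / (s2G + gxe_part + s2e / (ne * nr))
  } else NA_real_
  structure(list(
    trait = trait, mode = mode, gca = gca_tab, sca = sca_tab,
    varcomps = varcomps, ratio_gca_sca = gca_sca_ratio(varcomps),
    H2 = H2, n_environments = ne, n_locations = nl, n_replicates = nr,
    engine = eng, plan = plan,
    converged = if (mode == "random") eng$converged else TRUE
  ), class = "diallel_ca")
}

#' @export
print.diallel_ca <- function(x, digits = 3, ...) {
  cat("Combining-ability fit (", x$mode, " mode): trait ", x$trait,
      ", ", nrow(x$sca), " crosses, ", nrow(x$gca), " parents\n", sep = "")
  vc <- round(x$varcomps, digits)
  cat("  sigma2_GCA-parent   ", format(vc["sigma2_gca"]), "\n")
  cat("  sigma2_SCA          ", format(vc["sigma2_sca"]), "\n")
  if (is.finite(vc["sigma2_gca_location"])) {
    cat("  sigma2_GCA x L      ", format(vc["sigma2_gca_location"]), "\n")
  }
  cat("  sigma2_e            ", format(vc["sigma2_e"]), "\n")
  r <- x$ratio_gca_sca
  cat("  GCA/SCA ratio       ",
      if (is.na(r)) "-" else format(round(r, 2)), "\n")
  if (is.finite(x$H2)) cat("  H2 (hybrids)        ",
                           format(round(x$H2, 2)), "\n")
  invisible(x)
}

#' @export
summary.diallel_ca <- function(object, ...) {
  print(object)
  cat("\nGCA effects:\n")
  print(cbind(object$gca[, c("parent", "role")],
              round(object$gca[, c("effect", "se")], 3),
              stars = object$gca$stars), row.names = FALSE)
  cat("\nSCA effects:\n")
  print(cbind(object$sca[, "hybrid", drop = FALSE],
              round(object$sca[, c("effect", "se")], 3),
              stars = object$sca$stars), row.names = FALSE)
  invisible(object)
}

#' @export
coef.diallel_ca <- function(object, ...) {
  list(gca = stats::setNames(object$gca$effect, object$gca$parent),
       sca = stats::setNames(object$sca$effect, object$sca$hybrid))
}

#' Closed-form combining ability for a complete factorial of cell means
#'
#' Verification oracle restricted to a complete male x female grid of
#' cell means: \eqn{\mu} is the grand mean, male GCA the row-mean
#' deviations, female GCA the column-mean deviations, and SCA the
#' interaction residuals \eqn{cell - row - column + \mu}. The
#' reconstruction \eqn{\mu + g_i + g_j + s_ij} reproduces every cell
#' exactly and the effects sum to zero by construction.
#'
#' @param cell_means numeric matrix, rows = males, columns = females,
#'   no missing cells.
#' @return list \code{mu}, \code{gca_male}, \code{gca_female},
#'   \code{sca} (matrix).
#' @export
#' @examples
#' griffing_oracle(matrix(c(10, 14, 12, 16), 2, 2))
griffing_oracle <- function(cell_means) {
  M <- as.matrix(cell_means)
  if (any(!is.finite(M))) {
    stop("griffing_oracle() needs a complete grid of cell means",
         call. = FALSE)
  }
  mu <- mean(M)
  gm <- rowMeans(M) - mu
  gf <- colMeans(M) - mu
  sca <- M - outer(gm, gf, "+") - mu
  list(mu = mu, gca_male = gm, gca_female = gf, sca = sca)
}

#' Ratio of GCA to SCA variance
#'
#' \eqn{\sigma^2_{GCA}/\sigma^2_{SCA}}; the ratio is undefined (NA,
#' rendered "-") when the SCA component is zero. A ratio above one
#' indicates predominantly additive gene action.
#'
#' @param vc either a \code{diallel_ca} fit, or a named numeric vector
#'   containing \code{sigma2_gca} and \code{sigma2_sca}.
#' @return numeric ratio or NA.
#' @export
#' @examples
#' gca_sca_ratio(c(sigma2_gca = 0.07, sigma2_sca = 0.011))  # 6.36
gca_sca_ratio <- function(vc) {
  if (inherits(vc, "diallel_ca")) vc <- vc$varcomps
  g <- unname(vc["sigma2_gca"])
  s <- unname(vc["sigma2_sca"])
  if (is.na(g) || is.na(s) || g < 0 || s < 0) {
    stop("need nonnegative sigma2_gca and sigma2_sca", call. = FALSE)
  }
  if (s == 0) return(NA_real_)
  g / s
}
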