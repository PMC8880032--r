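#' @title Mid-parent and best-parent heterosis
#' @description Heterosis of an F1 hybrid relative to the mean of its
#'   two parents (MPH, relative heterosis) and to its better parent
#'   (BPH, heterobeltiosis), in percent, computed per cross x trait x
#'   scope from genotype BLUEs, with contrast-based significance tests
#'   on the fitted model.
#' @name heterosis
NULL

#' Mid-parent heterosis (percent)
#'
#' \eqn{MPH = 100 (F_1 - MP) / MP} with \eqn{MP = (P_1 + P_2)/2}.
#'
#' @param f1 hybrid value(s).
#' @param p1,p2 parent values.
#' @return percent; vectorized.
#' @export
#' @examples
#' mid_parent_heterosis(40.28, 37.62, 33.98)  # 12.51
mid_parent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  if (any(mp == 0)) stop("mid-parent value is zero", call. = FALSE)
  100 * (f1 - mp) / mp
}

#' Best-parent heterosis (percent)
#'
#' \eqn{BPH = 100 (F_1 - BP) / BP} where BP is the better parent: the
#' larger parental value when higher is better (the default for all
#' registry traits), otherwise the smaller.
#'
#' @param f1 hybrid value(s).
#' @param p1,p2 parent values.
#' @param higher_is_better direction of improvement.
#' @return percent; vectorized.
#' @export
#' @examples
#' best_parent_heterosis(38.62, 34.71, 34.53)  # 11.26
best_parent_heterosis <- function(f1, p1, p2, higher_is_better = TRUE) {
  bp <- if (isTRUE(higher_is_better)) pmax(p1, p2) else pmin(p1, p2)
  if (any(bp == 0)) stop("best-parent value is zero", call. = FALSE)
  100 * (f1 - bp) / bp
}

#' Heterosis table for all crosses of a plan
#'
#' One record per cross x trait x scope. Values come from a genotype
#' estimate table (typically BLUEs from [extract_blues()], or adjusted
#' means); combined-scope records must be fed combined-analysis BLUEs,
#' not averages of per-environment heterosis. Crosses whose hybrid or
#' either parent is missing for a scope are skipped with a warning.
#'
#' @param blues data frame with columns \code{genotype}, \code{trait},
#'   \code{estimate} and optionally \code{scope} (default
#'   \code{"combined"}).
#' @param plan a [crossing_plan()].
#' @param traits optional subset of traits.
#' @param registry trait registry supplying \code{higher_is_better}.
#' @return data frame of class \code{heterosis_table} with columns
#'   \code{hybrid}, \code{female}, \code{male}, \code{trait},
#'   \code{scope}, \code{f1}, \code{mp}, \code{bp}, \code{mph},
#'   \code{bph} (full precision; the print method rounds to 2 dp).
#' @export
heterosis_table <- function(blues, plan, traits = NULL,
                            registry = trait_registry()) {
  stopifnot(inherits(plan, "crossing_plan"))
  stopifnot(all(c("genotype", "trait", "estimate") %in% names(blues)))
  if (is.null(blues$scope)) blues$scope <- "combined"
  if (is.null(traits)) traits <- unique(blues$trait)
  blues <- blues[blues$trait %in% traits, , drop = FALSE]
  out <- list()
  for (sc in unique(blues$scope)) {
    for (tr in unique(blues$trait[blues$scope == sc])) {
      sub <- blues[blues$scope == sc & blues$trait == tr, , drop = FALSE]
      est <- stats::setNames(sub$estimate, sub$genotype)
      hib <- registry$higher_is_better[match(tr, registry$name)]
      for (k in seq_len(nrow(plan$crosses))) {
        hy <- plan$crosses$hybrid_id[k]
        fe <- plan$crosses$female_id[k]
        ma <- plan$crosses$male_id[k]
        if (!all(c(hy, fe, ma) %in% names(est))) {
          warning("skipping cross ", hy, " (", tr, ", ", sc,
                  "): hybrid or parent estimate missing")
          next
        }
        f1 <- est[[hy]]; p1 <- est[[fe]]; p2 <- est[[ma]]
        out[[length(out) + 1L]] <- data.frame(
          hybrid = hy, female = fe, male = ma, trait = tr, scope = sc,
          f1 = f1, mp = (p1 + p2) / 2,
          bp = if (isTRUE(hib)) max(p1, p2) else min(p1, p2),
          mph = mid_parent_heterosis(f1, p1, p2),
          bph = best_parent_heterosis(f1, p1, p2, hib),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(hybrid = character(0), female = character(0),
               male = character(0), trait = character(0),
               scope = character(0), f1 = numeric(0), mp = numeric(0),
               bp = numeric(0), mph = numeric(0), bph = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("heterosis_table", "data.frame")
  res
}

#' @export
print.heterosis_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("f1", "mp", "bp", "mph", "bph")) y[[cl]] <- round(y[[cl]], 2)
  print(y, ...)
  invisible(x)
}

#' Significance of a heterosis contrast
#'
#' Tests the linear contrast \eqn{F_1 - (P_1 + P_2)/2} (mid-parent) or
#' \eqn{F_1 - BP} (best-parent, better parent decided from the fitted
#' BLUEs) on a fixed-genotype mixed-model fit, using the REML
#' fixed-effect covariance and a t reference with the fit's residual
#' degrees of freedom. No multiplicity correction is applied.
#'
#' @param fit [fit_reml()] result with genotype fixed, containing the
#'   hybrid and both parents.
#' @param hybrid,female,male genotype ids of the cross.
#' @param type "mid" or "best".
#' @param higher_is_better direction used to pick the best parent.
#' @return data frame: estimate (trait units), se, t, df, p_value.
#' @export
heterosis_significance <- function(fit, hybrid, female, male,
                                   type = c("mid", "best"),
                                   higher_is_better = TRUE) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$genotype_role != "fixed") {
    stop("heterosis contrasts need a fixed-genotype fit", call. = FALSE)
  }
  beta <- fit$engine$beta
  ids <- c(hybrid, female, male)
  if (!all(ids %in% names(beta))) {
    stop("non-estimable contrast: missing genotype(s) ",
         paste(setdiff(ids, names(beta)), collapse = ", "), call. = FALSE)
  }
  cvec <- stats::setNames(rep(0, length(beta)), names(beta))
  if (type == "mid") {
    cvec[hybrid] <- 1
    cvec[female] <- cvec[female] - 0.5
    cvec[male] <- cvec[male] - 0.5
  } else {
    pick <- if (isTRUE(higher_is_better)) {
      if (beta[female] >= beta[male]) female else male
    } else {
      if (beta[female] <= beta[male]) female else male
    }
    cvec[hybrid] <- 1
    cvec[pick] <- cvec[pick] - 1
  }
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% fit$engine$cov_beta %*% cvec))
  df <- fit$edf_residual
  tval <- if (se > 0) est / se else sign(est) * Inf
  p <- if (se > 0) 2 * stats::pt(-abs(tval), df) else as.numeric(est != 0) * 0
  if (se == 0 && est == 0) p <- 1
  data.frame(hybrid = hybrid, type = type, estimate = est, se = se,
             t = tval, df = df, p_value = p, stringsAsFactors = FALSE)
}
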