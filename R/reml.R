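#' @title REML engine for Gaussian variance-component models
#' @description Restricted maximum likelihood estimation for models of
#'   the form \code{y = X b + sum_r Z_r u_r + e} with
#'   \code{u_r ~ N(0, s2_r I)} and \code{e ~ N(0, s2_e I)}, solved
#'   through Henderson's mixed-model equations. Estimation runs EM
#'   iterations first (each EM step cannot decrease the restricted
#'   log-likelihood), then polishes the profiled restricted likelihood
#'   over the log variance ratios with a quasi-Newton step, and pins
#'   vanishing components at exactly zero with a boundary flag.
#' @name reml-engine
NULL

# Profiled -2 * restricted log-likelihood at variance ratios
# gamma_r = s2_r / s2_e, via the MME identity
#   -2 lR = (n-p) log 2pi + (n-p) log s2e_hat + (n-p)
#           + sum_r q_r log gamma_r + log |M_gamma|
# with M_gamma = [X Z]'[X Z] + diag(0_p, 1/gamma) and
# s2e_hat = y' P y / (n - p) = (y'y - coef' W'y) / (n - p).
reml_profile <- function(log_gamma, env) {
  gamma <- exp(log_gamma)
  M <- env$WtW
  diag(M) <- diag(M) + c(rep(0, env$p),
                         unlist(lapply(seq_along(env$blocks), function(r)
                           rep(1 / gamma[r], length(env$blocks[[r]])))))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e300))
  coef <- backsolve(ch, forwardsolve(t(ch), env$Wty))
  ypPy <- env$yty - sum(coef * env$Wty)
  if (ypPy <= 0) return(list(value = 1e300))
  np <- env$n - env$p
  s2e <- ypPy / np
  val <- np * log(2 * pi) + np * log(s2e) + np +
    sum(env$qs * log_gamma) + 2 * sum(log(diag(ch)))
  list(value = val, coef = coef, s2e = s2e, chol = ch)
}

#' Fit a variance-component model by REML
#'
#' Low-level fitting routine used by [fit_reml()] and
#' [fit_combining_ability()]. Takes the response, a fixed-effect design
#' matrix and a named list of random-effect design matrices; returns
#' variance components, fixed-effect estimates with standard errors,
#' random-effect predictions (BLUPs) with prediction error variances,
#' and the restricted log-likelihood.
#'
#' Aliased fixed-effect columns are dropped (recorded in
#' \code{dropped_fixed}); components whose estimate collapses below
#' \code{pin_tol} times the total variance are fixed at zero and flagged
#' in \code{boundary}.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (a column of ones if only an
#'   intercept is wanted).
#' @param Z_list named list of random-effect design matrices (may be
#'   empty, giving ordinary least squares).
#' @param max_iter maximum EM iterations before the polish step.
#' @param tol_vc relative convergence tolerance on variance components.
#' @param tol_ll absolute convergence tolerance on the restricted
#'   log-likelihood.
#' @param pin_tol relative threshold under which a component is pinned
#'   to zero.
#' @return a list of class \code{reml_engine_fit}; see Details.
#' @export
reml_engine <- function(y, X, Z_list = list(), max_iter = 200L,
                        tol_vc = 1e-8, tol_ll = 1e-9, pin_tol = 1e-7) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (length(Z_list)) {
    stopifnot(!is.null(names(Z_list)), all(nzchar(names(Z_list))))
    for (Z in Z_list) stopifnot(nrow(Z) == n)
  }

  # full-rank reduction of X via pivoted QR
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  dropped_fixed <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, sort(keep), drop = FALSE]
  p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect parameters",
                   call. = FALSE)

  terms <- names(Z_list)
  R <- length(Z_list)
  qs_all <- vapply(Z_list, ncol, 0L)

  ols <- function(active) {
    Zs <- Z_list[active]
    W <- do.call(cbind, c(list(X), lapply(Zs, unname)))
    env <- list(WtW = crossprod(W), Wty = drop(crossprod(W, y)),
                yty = sum(y * y), n = n, p = p,
                qs = qs_all[active],
                blocks = {
                  off <- p
                  bl <- lapply(Zs, function(Z) {
                    ix <- off + seq_len(ncol(Z)); off <<- off + ncol(Z); ix
                  })
                  bl
                })
    env
  }

  vartot <- stats::var(y)
  if (!is.finite(vartot) || vartot <= 0) vartot <- max(mean(y^2), 1)

  # residual-only (OLS) path, also used for degenerate data
  ols_fit <- stats::lm.fit(X, y)
  rss0 <- sum(ols_fit$residuals^2)
  if (R == 0L || rss0 < 1e-12 * max(1, sum(y^2))) {
    s2e <- rss0 / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    ll <- -0.5 * ((n - p) * log(2 * pi) +
                    (n - p) * log(max(s2e, .Machine$double.xmin)) +
                    (n - p) + 2 * sum(log(diag(chol(crossprod(X))))))
    out <- list(
      sigma2 = stats::setNames(c(rep(0, R), s2e), c(terms, "residual")),
      beta = stats::setNames(ols_fit$coefficients, colnames(X)),
      se_beta = stats::setNames(sqrt(pmax(s2e * diag(XtXi), 0)), colnames(X)),
      cov_beta = s2e * XtXi,
      u = stats::setNames(lapply(Z_list, function(Z)
        stats::setNames(rep(0, ncol(Z)), colnames(Z))), terms),
      pev = stats::setNames(lapply(Z_list, function(Z)
        stats::setNames(rep(0, ncol(Z)), colnames(Z))), terms),
      loglik = if (R == 0L) ll else NA_real_,
      loglik_trace = numeric(0),
      converged = TRUE, n_iter = 0L, n = n, p = p, edf_residual = n - p,
      boundary = stats::setNames(rep(R > 0L, R), terms),
      dropped_fixed = dropped_fixed, fitted = drop(X %*% ols_fit$coefficients)
    )
    class(out) <- "reml_engine_fit"
    return(out)
  }

  active <- rep(TRUE, R)
  sigma2 <- rep(vartot / (R + 1), R)
  s2e <- vartot / (R + 1)
  trace <- numeric(0)
  iter <- 0L

  repeat {
    env <- ols(active)
    qa <- qs_all[active]
    nact <- sum(active)
    gamma <- sigma2[active] / s2e

    em_pass <- function(gamma, s2e, n_em) {
      for (it in seq_len(n_em)) {
        iter <<- iter + 1L
        M <- env$WtW
        diag(M) <- diag(M) + c(rep(0, p), unlist(
          lapply(seq_len(nact), function(r)
            rep(s2e / (gamma[r] * s2e), length(env$blocks[[r]])))))
        ch <- chol(M)
        Cinv <- chol2inv(ch)
        coef <- drop(Cinv %*% env$Wty)
        s2r <- gamma * s2e
        new_s2r <- vapply(seq_len(nact), function(r) {
          ix <- env$blocks[[r]]
          (sum(coef[ix]^2) + s2e * sum(diag(Cinv)[ix])) / length(ix)
        }, 0)
        new_s2e <- (env$yty - sum(coef * env$Wty)) / (n - p)
        prof <- reml_profile(log(pmax(new_s2r / new_s2e, 1e-14)), env)
        trace <<- c(trace, -0.5 * prof$value)
        gamma <- pmax(new_s2r, 1e-14 * vartot) / new_s2e
        s2e <- new_s2e
        rel <- max(abs(c(new_s2r, new_s2e) - c(s2r, s2e))) /
          max(vartot, 1e-12)
        if (rel < tol_vc) break
        if (any(new_s2r < pin_tol * vartot)) break
      }
      list(gamma = gamma, s2e = s2e)
    }

    em <- em_pass(gamma, s2e, min(25L, max_iter))
    gamma <- em$gamma
    s2e <- em$s2e

    # quasi-Newton polish of the profiled restricted likelihood
    obj <- function(lg) reml_profile(lg, env)$value
    opt <- stats::nlminb(log(pmax(gamma, 1e-12)), obj,
                         lower = log(1e-12), upper = log(1e10),
                         control = list(iter.max = as.integer(max_iter),
                                        rel.tol = 1e-14, x.tol = 1e-12))
    gamma <- exp(opt$par)
    prof <- reml_profile(opt$par, env)
    s2e <- prof$s2e
    trace <- c(trace, -0.5 * prof$value)
    sigma2[active] <- gamma * s2e

    pin <- active & (sigma2 < pin_tol * vartot)
    if (!any(pin)) {
      converged <- opt$convergence == 0 || opt$iterations < max_iter
      break
    }
    sigma2[pin] <- 0
    active <- active & !pin
    if (!any(active)) {
      # all components pinned: residual-only refit
      s2e <- rss0 / (n - p)
      env <- NULL
      converged <- TRUE
      break
    }
  }

  # final solve at the optimum
  if (any(active)) {
    env <- ols(active)
    prof <- reml_profile(log(sigma2[active] / s2e), env)
    Cinv <- chol2inv(prof$chol)
    coef <- prof$coef
    s2e <- prof$s2e
    sigma2[active] <- exp(log(sigma2[active] / s2e)) * s2e  # unchanged
    ll <- -0.5 * prof$value
    cov_all <- s2e * Cinv
    beta <- coef[seq_len(p)]
    u <- stats::setNames(vector("list", R), terms)
    pev <- stats::setNames(vector("list", R), terms)
    ia <- which(active)
    for (r in seq_len(R)) {
      cn <- colnames(Z_list[[r]])
      if (active[r]) {
        ix <- env$blocks[[match(r, ia)]]
        u[[r]] <- stats::setNames(coef[ix], cn)
        pev[[r]] <- stats::setNames(pmax(diag(cov_all)[ix], 0), cn)
      } else {
        u[[r]] <- stats::setNames(rep(0, qs_all[r]), cn)
        pev[[r]] <- stats::setNames(rep(0, qs_all[r]), cn)
      }
    }
    Zact <- do.call(cbind, lapply(Z_list[active], unname))
    fitted <- drop(X %*% beta + Zact %*% coef[-seq_len(p)])
    cov_beta <- cov_all[seq_len(p), seq_len(p), drop = FALSE]
  } else {
    XtXc <- chol(crossprod(X))
    XtXi <- chol2inv(XtXc)
    beta <- stats::lm.fit(X, y)$coefficients
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) + (n - p) +
                    2 * sum(log(diag(XtXc))))
    cov_beta <- s2e * XtXi
    u <- stats::setNames(lapply(Z_list, function(Z)
      stats::setNames(rep(0, ncol(Z)), colnames(Z))), terms)
    pev <- stats::setNames(lapply(Z_list, function(Z)
      stats::setNames(rep(0, ncol(Z)), colnames(Z))), terms)
    fitted <- drop(X %*% beta)
  }

  out <- list(
    sigma2 = stats::setNames(c(sigma2, s2e), c(terms, "residual")),
    beta = stats::setNames(beta, colnames(X)),
    se_beta = stats::setNames(sqrt(pmax(diag(cov_beta), 0)), colnames(X)),
    cov_beta = cov_beta,
    u = u, pev = pev,
    loglik = ll, loglik_trace = trace,
    converged = isTRUE(converged), n_iter = iter,
    n = n, p = p, edf_residual = n - p,
    boundary = stats::setNames(!active, terms),
    dropped_fixed = dropped_fixed, fitted = fitted
  )
  class(out) <- "reml_engine_fit"
  out
}

#' Likelihood-ratio tests for variance components
#'
#' Refits the model with each random term dropped in turn and compares
#' restricted log-likelihoods. P-values use the 50:50 mixture of a
#' point mass at zero and a chi-square with 1 df, the usual reference
#' for a variance component tested on its boundary.
#'
#' @param y,X,Z_list as in [reml_engine()].
#' @param fit an existing full-model fit (refitted if missing).
#' @return data frame with columns \code{term}, \code{sigma2},
#'   \code{lrt}, \code{p_value}, \code{stars}.
#' @export
varcomp_tests <- function(y, X, Z_list, fit = NULL) {
  if (is.null(fit)) fit <- reml_engine(y, X, Z_list)
  terms <- names(Z_list)
  res <- data.frame(term = terms, sigma2 = fit$sigma2[terms],
                    lrt = NA_real_, p_value = NA_real_,
                    stars = "", stringsAsFactors = FALSE)
  for (r in seq_along(terms)) {
    red <- reml_engine(y, X, Z_list[-r])
    lrt <- max(0, 2 * (fit$loglik - red$loglik))
    res$lrt[r] <- lrt
    res$p_value[r] <- if (lrt <= 0) 1 else
      0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  res$stars <- significance_stars(res$p_value)
  rownames(res) <- NULL
  res
}

#' Star notation for p-values
#'
#' Thresholds 0.05, 0.01, 0.001, 0.0001 map to one to four stars.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  cut_pts <- c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1)
  labs <- c("****", "***", "**", "*", "")
  out <- labs[as.integer(cut(p, cut_pts, labels = FALSE,
                             include.lowest = TRUE, right = TRUE))]
  out[is.na(p)] <- ""
  out
}
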