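# Gauss-Hermite nodes/weights for weight function exp(-z^2).
gh_nodes <- function(order) {
  if (order == 1) return(list(x = 0, w = sqrt(pi)))
  pracma::gaussHermite(order)
}

# Marginal log-likelihood by adaptive Gauss-Hermite quadrature. Each block's
# integrand is recentred at its conditional mode (vectorized Newton across
# all blocks; the conditional log-density is strictly concave so the
# iteration is safe) and rescaled by the curvature there, then integrated on
# `quad` nodes. sigma = 0 reduces exactly to the independent-binomial
# log-likelihood; order 1 is the Laplace approximation.
aghq_loglik <- function(beta, sigma, X, y, n, block, quad) {
  eta <- drop(X %*% beta)
  if (sigma <= 0)
    return(sum(stats::dbinom(y, n, stats::plogis(eta), log = TRUE)))
  sig2 <- sigma^2
  blk <- as.integer(block)
  nb <- nlevels(block)
  u <- numeric(nb)
  for (it in 1:50) {
    p <- stats::plogis(eta + u[blk])
    g <- rowsum(y - n * p, blk, reorder = TRUE)[, 1] - u / sig2
    H <- -rowsum(n * p * (1 - p), blk, reorder = TRUE)[, 1] - 1 / sig2
    step <- g / H
    u <- u - step
    if (max(abs(step)) < 1e-12) break
  }
  p <- stats::plogis(eta + u[blk])
  tau <- 1 / sqrt(rowsum(n * p * (1 - p), blk, reorder = TRUE)[, 1] + 1 / sig2)
  K <- length(quad$x)
  hk <- matrix(0, nb, K)  # blocks x nodes
  for (k in seq_len(K)) {
    u_k <- u + sqrt(2) * tau * quad$x[k]
    hk[, k] <- rowsum(stats::dbinom(y, n, stats::plogis(eta + u_k[blk]),
                                    log = TRUE), blk, reorder = TRUE)[, 1] -
      u_k^2 / (2 * sig2) + quad$x[k]^2
  }
  M <- apply(hk, 1, max)
  sum(M + log(exp(hk - M) %*% quad$w) + log(sqrt(2) * tau)) -
    nb * (log(sigma) + 0.5 * log(2 * pi))
}

# Detect complete separation: a factor level whose outcomes are all removed
# or all present makes the corresponding logit coefficient infinite.
check_separation <- function(transects, vars) {
  for (v in vars) {
    f <- transects[[v]]
    if (is.null(f) || length(unique(f)) < 2) next
    for (lev in unique(as.character(f))) {
      y <- transects$removed[f == lev]
      n <- transects$n_stations[f == lev]
      if (all(y == 0) || all(y == n))
        stop(sprintf("complete separation: %s '%s' has all outcomes %s",
                     v, lev, if (all(y == 0)) "present" else "removed"),
             call. = FALSE)
    }
  }
}

#' Fit a binomial logit mixed model to sentinel-prey transects
#'
#' Maximum-likelihood fit of removed-out-of-five counts with categorical fixed
#' effects and a single Gaussian random intercept over spatial blocks. The
#' marginal likelihood integrates the block intercept out by adaptive
#' Gauss-Hermite quadrature (`nAGQ` nodes; `nAGQ = 1` is the Laplace
#' approximation). The random-intercept standard deviation is parameterized on
#' the log scale; the fit is profiled against the boundary `sigma_b = 0`
#' (plain independent-binomial likelihood), and the better of the interior and
#' boundary solutions is returned. Estimation is ML throughout (not REML-like)
#' so nested fixed-effect specifications are comparable by likelihood ratio.
#'
#' @param transects A `sentinel` data frame (see [as_sentinel()]).
#' @param fixed Fixed-effect formula over columns of `transects`, e.g.
#'   `~ group * site` (default) or `~ site` for the no-treatment null.
#' @param ref Reference level for the treatment factor (default `"control"`);
#'   relabeling changes the coefficients but not fitted probabilities, LRT
#'   statistics or contrast z values.
#' @param re Name of the random-intercept grouping column (default
#'   `"block"`, the site x vineyard-half spatial block). `re = "transect"`
#'   adds an observation-level intercept usable as an overdispersion term.
#' @param nAGQ Quadrature order (default 15).
#' @param sigma_fixed Fix `sigma_b` at this value instead of estimating it
#'   (0 gives the independent-binomial fit); `NULL` (default) estimates it.
#' @param start Optional start values for the fixed effects.
#' @return A `glmm_fit` with elements `coefficients`, `sigma_b`, `logLik`,
#'   `deviance` (`-2 logLik`), `vcov` (observed-information covariance of the
#'   fixed effects), `converged`, `boundary`, `n_params`
#'   (`length(coefficients) + 1`), plus the design bookkeeping needed for
#'   contrasts and refits.
#' @export
#' @examples
#' tr <- simulate_sentinel(sim_config(seed = 3))
#' fit <- fit_binomial_glmm(tr, ~ group)
#' fit$coefficients
fit_binomial_glmm <- function(transects, fixed = ~ group * site, re = "block",
                              nAGQ = 15, sigma_fixed = NULL, start = NULL,
                              ref = "control") {
  transects <- as_sentinel(as.data.frame(transects))
  transects$group <- droplevels(transects$group)
  if (ref %in% levels(transects$group))
    transects$group <- stats::relevel(transects$group, ref = ref)
  if (nrow(transects) < 2) stop("need at least 2 transects", call. = FALSE)
  if (re == "transect") transects$transect <- seq_len(nrow(transects))
  if (is.null(transects[[re]])) stop("unknown grouping column: ", re,
                                     call. = FALSE)
  tvars <- all.vars(fixed)
  check_separation(transects, tvars)

  X <- stats::model.matrix(fixed, data = transects)
  y <- transects$removed
  n <- transects$n_stations
  block <- factor(transects[[re]])
  if (nlevels(block) < 1) stop("need at least 1 block", call. = FALSE)
  quad <- gh_nodes(nAGQ)
  p <- ncol(X)

  # sigma = 0 profile: plain binomial logistic fit, used as start values,
  # boundary candidate and the sigma_fixed = 0 path.
  g0 <- stats::glm.fit(X, cbind(y, n - y),
                       family = stats::binomial("logit"),
                       control = list(epsilon = 1e-12, maxit = 100))
  beta0 <- g0$coefficients
  nll0 <- function(b) -aghq_loglik(b, 0, X, y, n, block, quad)
  o0 <- stats::optim(beta0, nll0, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500))
  ll0 <- -o0$value

  make_fit <- function(beta, sigma, ll, conv, boundary, vcov_mat) {
    beta <- stats::setNames(as.numeric(beta), colnames(X))
    sigma <- unname(sigma)
    structure(list(coefficients = beta, sigma_b = sigma, logLik = ll,
                   deviance = -2 * ll, vcov = vcov_mat, converged = conv,
                   boundary = boundary, n_params = p + 1L, nAGQ = nAGQ,
                   fixed = fixed, re = re, nobs = nrow(transects),
                   data = transects, X = X),
              class = "glmm_fit")
  }
  vcov_beta_at <- function(beta, sigma) {
    H <- stats::optimHess(beta, function(b)
      -aghq_loglik(b, sigma, X, y, n, block, quad))
    solve(H)
  }

  if (!is.null(sigma_fixed)) {
    if (sigma_fixed == 0)
      return(make_fit(o0$par, 0, ll0, o0$convergence == 0, TRUE,
                      vcov_beta_at(o0$par, 0)))
    nllf <- function(b) -aghq_loglik(b, sigma_fixed, X, y, n, block, quad)
    of <- stats::optim(start %||% o0$par, nllf, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
    return(make_fit(of$par, sigma_fixed, -of$value, of$convergence == 0,
                    FALSE, vcov_beta_at(of$par, sigma_fixed)))
  }

  # joint fit over (beta, log sigma): derivative-free sweep, then
  # quasi-Newton polish
  nll <- function(theta) -aghq_loglik(theta[1:p], exp(theta[p + 1]),
                                      X, y, n, block, quad)
  th0 <- c(start %||% beta0, log(0.3))
  onm <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 2000))
  obf <- stats::optim(onm$par, nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  th <- obf$par
  sigma <- exp(th[p + 1])
  ll <- -obf$value
  conv <- obf$convergence == 0 && onm$convergence == 0

  # boundary handling: if the interior solution does not beat sigma = 0
  # (or collapsed onto it), report the boundary fit.
  if (ll <= ll0 + 1e-8 || sigma < 1e-4)
    return(make_fit(o0$par, 0, ll0, o0$convergence == 0, TRUE,
                    vcov_beta_at(o0$par, 0)))

  H <- stats::optimHess(th, nll)
  V <- tryCatch(solve(H), error = function(e) NULL)
  vb <- if (is.null(V)) vcov_beta_at(th[1:p], sigma) else V[1:p, 1:p, drop = FALSE]
  make_fit(th[1:p], sigma, ll, conv, FALSE, vb)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Binomial logit mixed model (AGHQ order %d%s)\n", x$nAGQ,
              if (x$boundary) ", sigma_b at boundary 0" else ""))
  cat("Fixed effects:", deparse(x$fixed), "  random intercept:", x$re, "\n")
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = round(est, 4), se = round(se, 4),
                   z = round(est / se, 3)))
  cat(sprintf("sigma_b = %.4f   logLik = %.4f   n = %d%s\n", x$sigma_b,
              x$logLik, x$nobs,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  invisible(x)
}

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' Compares a full and a nested null fit by `chi2 = deviance_null -
#' deviance_full` on `df = ` the difference in parameter counts, referred to
#' the upper tail of the chi-square law. Dropping the 3-level treatment term
#' gives `df = 2`.
#'
#' @param full,null `glmm_fit` objects on the same data; the null's fixed
#'   terms must be a subset of the full's and both must use the same random
#'   grouping.
#' @return An `lrt_result` data frame with columns `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "glmm_fit"), inherits(null, "glmm_fit"))
  if (full$nobs != null$nobs || full$re != null$re)
    stop("fits are not on the same data / random-effect structure",
         call. = FALSE)
  tf <- attr(stats::terms(full$fixed), "term.labels")
  tn <- attr(stats::terms(null$fixed), "term.labels")
  if (!all(tn %in% tf) || full$n_params < null$n_params)
    stop("null model is not nested in the full model", call. = FALSE)
  if (!full$converged || !null$converged)
    stop("cannot test: a fit did not converge", call. = FALSE)
  chi2 <- max(0, null$deviance - full$deviance)
  df <- full$n_params - null$n_params
  # identical specifications: the degenerate identity comparison
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(data.frame(chi2 = chi2, df = df, p = p),
            class = c("lrt_result", "data.frame"))
}
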