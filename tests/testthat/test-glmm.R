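# Independent brute-force MLE for the no-random-effect binomial logit model:
# direct optimisation of the likelihood written from scratch.
bruteforce_mle <- function(X, y, n) {
  nll <- function(b) -sum(dbinom(y, n, plogis(drop(X %*% b)), log = TRUE))
  o <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 5000))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  o$par
}

test_that("sigma = 0 fit equals the closed-form two-group logistic MLE", {
  tr <- two_group_sentinel()
  fit <- fit_binomial_glmm(tr, ~ group, sigma_fixed = 0)
  p_hat <- tapply(tr$removed, droplevels(tr$group), sum) /
    tapply(tr$n_stations, droplevels(tr$group), sum)
  expect_equal(unname(fit$coefficients),
               unname(c(qlogis(p_hat[1]), qlogis(p_hat[2]) - qlogis(p_hat[1]))),
               tolerance = 1e-8)
  # marginal likelihood at sigma = 0 is exactly the plain binomial likelihood
  expect_equal(fit$logLik,
               sum(dbinom(tr$removed, tr$n_stations,
                          plogis(drop(fit$X %*% fit$coefficients)),
                          log = TRUE)))
})

test_that("sigma = 0 fit matches a brute-force independent-binomial MLE", {
  tr <- three_group_sentinel(seed = 12)
  for (form in list(~ group, ~ group + site)) {
    fit <- fit_binomial_glmm(tr, form, sigma_fixed = 0)
    oracle <- bruteforce_mle(fit$X, tr$removed, tr$n_stations)
    expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-6)
  }
})

test_that("AGHQ fit agrees with an independent mixed-model implementation", {
  cfg <- sim_config(seed = 7, sentinel = list(sigma_b = 1.0,
                                              transects_per_group = 8))
  tr <- simulate_sentinel(cfg)
  fit <- fit_binomial_glmm(tr, ~ group, nAGQ = 15)
  g <- lme4::glmer(cbind(removed, n_stations - removed) ~ group + (1 | block),
                   data = tr, family = binomial, nAGQ = 15)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(g)),
               tolerance = 1e-4)
  expect_equal(fit$sigma_b, sqrt(unlist(lme4::VarCorr(g))[[1]]),
               tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(as.matrix(vcov(g))))), tolerance = 1e-3)
  # likelihood-ratio statistics agree (absolute logLik differs by the
  # binomial normalizing constant, which cancels between nested fits)
  null <- fit_binomial_glmm(tr, ~ 1, nAGQ = 15)
  gn <- lme4::glmer(cbind(removed, n_stations - removed) ~ 1 + (1 | block),
                    data = tr, family = binomial, nAGQ = 15)
  expect_equal(2 * (fit$logLik - null$logLik),
               2 * (as.numeric(logLik(g)) - as.numeric(logLik(gn))),
               tolerance = 1e-5)
})

test_that("log-likelihood is stable across quadrature orders", {
  tr <- simulate_sentinel(sim_config(seed = 7,
                                     sentinel = list(sigma_b = 1.0)))
  f15 <- fit_binomial_glmm(tr, ~ group, nAGQ = 15)
  # evaluate the order-25 likelihood at the order-15 optimum
  f25 <- fit_binomial_glmm(tr, ~ group, nAGQ = 25,
                           sigma_fixed = f15$sigma_b,
                           start = f15$coefficients)
  expect_lt(abs(f15$logLik - f25$logLik), 1e-6)
  # Laplace (order 1) is close but not required to be identical
  f1 <- fit_binomial_glmm(tr, ~ group, nAGQ = 1)
  expect_lt(abs(f1$logLik - f15$logLik), 0.1)
})

test_that("likelihood-ratio test recovers nesting structure and df", {
  tr <- three_group_sentinel(seed = 3)
  full <- fit_binomial_glmm(tr, ~ group + site)
  null <- fit_binomial_glmm(tr, ~ site)
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$df, 2)          # dropping a 3-level factor
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$p, pchisq(lrt$chi2, 2, lower.tail = FALSE))
  # chi2 from an independent refit equals the stored value
  full2 <- fit_binomial_glmm(tr, ~ group + site)
  null2 <- fit_binomial_glmm(tr, ~ site)
  expect_equal(likelihood_ratio_test(full2, null2)$chi2, lrt$chi2,
               tolerance = 1e-8)
  # identity comparison: chi2 = 0, p = 1
  id <- likelihood_ratio_test(full, full2)
  expect_equal(id$chi2, 0, tolerance = 1e-6)
  expect_equal(id$p, 1)
  # interaction term adds 2 params
  inter <- fit_binomial_glmm(tr, ~ group * site)
  expect_equal(likelihood_ratio_test(inter, full)$df, 2)
  expect_error(likelihood_ratio_test(null, full), "not nested")
  expect_error(
    likelihood_ratio_test(fit_binomial_glmm(tr, ~ group),
                          fit_binomial_glmm(tr, ~ site)), "not nested")
})

test_that("complete separation is reported with the offending group", {
  tr <- two_group_sentinel(y1 = rep(0, 6), y2 = c(3, 4, 3, 2, 4, 3))
  expect_error(fit_binomial_glmm(tr, ~ group), "control")
  tr2 <- two_group_sentinel(y1 = c(1, 2, 2, 3, 1, 2), y2 = rep(5, 6))
  expect_error(fit_binomial_glmm(tr2, ~ group), "nestbox_random")
})

test_that("relabeling the reference level preserves the fit", {
  tr <- three_group_sentinel(seed = 9)
  f_ctrl <- fit_binomial_glmm(tr, ~ group, ref = "control")
  f_act <- fit_binomial_glmm(tr, ~ group, ref = "active_nest")
  # coefficients differ, fitted quantities do not
  expect_equal(f_ctrl$logLik, f_act$logLik, tolerance = 1e-6)
  expect_equal(f_ctrl$sigma_b, f_act$sigma_b, tolerance = 1e-4)
  eta_c <- drop(f_ctrl$X %*% f_ctrl$coefficients)
  eta_a <- drop(f_act$X %*% f_act$coefficients)
  expect_equal(plogis(eta_c), plogis(eta_a), tolerance = 1e-5)
  # contrast |z| values are the same set
  z_c <- sort(abs(pairwise_contrasts(f_ctrl, adjust = "none")$z))
  z_a <- sort(abs(pairwise_contrasts(f_act, adjust = "none")$z))
  expect_equal(z_c, z_a, tolerance = 1e-4)
})

test_that("fixed effects are recovered without bias on simulated data", {
  # moderate simulation study at the calibrated effect sizes
  nrep <- 60
  est <- matrix(NA_real_, nrep, 3)
  truth <- sim_config(seed = 1)$sentinel$beta
  for (i in seq_len(nrep)) {
    cfg <- sim_config(seed = 20000 + i, n_sites = 4,
                      sentinel = list(sigma_b = 0.5,
                                      transects_per_group = 10,
                                      active_per_site = rep(8, 4)))
    tr <- simulate_sentinel(cfg)
    f <- fit_binomial_glmm(tr, ~ group, nAGQ = 9)
    est[i, ] <- f$coefficients
  }
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_true(all(abs(bias) <= 4 * mc_se))
})
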