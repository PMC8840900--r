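test_that("a small synthetic fit converges with exact AIC bookkeeping", {
  cfg <- simConfig(n_sites = 30, n_years = 4, seed = 21)
  sim <- simulateObservations(cfg)
  fit <- fitSGM(sim$samples, spec = sgmSpec(), seed = 21)
  expect_true(fit$converged)
  expect_identical(fit$aic, 2 * fit$n_fixed + 2 * fit$nll)
  expect_true(all(fit$d_hat > 0))
  expect_equal(dim(fit$d_hat), c(30L, 4L))
  expect_equal(length(fit$fields$omega), 30L)
  # the field split reassembles the collapsed latent exactly
  expect_equal(fit$fields$omega + fit$fields$epsilon, unclass(fit$fields$eta),
               ignore_attr = TRUE)
  expect_output(print(fit), "Spatial Gompertz")
  fe <- fixedEffects(fit, betas = TRUE)
  expect_true(all(paste0("beta_", fit$years) %in% fe$term))
})

test_that("fitSGM validates its inputs", {
  cfg <- simConfig(n_sites = 10, n_years = 3, seed = 22)
  s <- simulateObservations(cfg)$samples
  expect_error(fitSGM(s[s$year == 2001, ]), "2 years")
  s2 <- s; s2$b[1] <- -1
  expect_error(fitSGM(s2), "negative biomass")
  s3 <- s; s3$tit <- 1
  expect_error(fitSGM(s3), "zero variance")
  s4 <- s[, setdiff(names(s), "pc")]
  expect_error(fitSGM(s4, spec = sgmSpec(include_pc = TRUE)), "covariate")
})

test_that("Wald significance follows the closed-interval rule", {
  s <- significance(0.025, 0.02 / 1.959964)
  expect_equal(s$ci, c(0.005, 0.045), tolerance = 1e-10)
  expect_true(s$significant)
  expect_false(significance(0, 1)$significant)
  # an interval touching zero encompasses it
  est <- 1.959964 * 0.5
  expect_equal(significance(est, 0.5)$ci[1], 0, tolerance = 1e-12)
  expect_false(significance(est, 0.5)$significant)
})

fake_fit <- function(aic, gamma2, se2, fp = c(n = 10, sum_b = 1, sum_b2 = 1),
                     converged = TRUE) {
  list(aic = aic, converged = converged, data_fingerprint = fp,
       lay = list(names = c("gamma_tit", "gamma_tit2")),
       theta = c(gamma_tit = 0.1, gamma_tit2 = gamma2),
       se_theta = c(gamma_tit = 0.01, gamma_tit2 = se2))
}

test_that("quadratic model selection needs both lower AIC and significance", {
  strip <- function(x) { attr(x, "selection") <- NULL; x }
  fl <- fake_fit(110, NA, NA)
  # quadratic effect with CI [-0.045, -0.014]: chosen when AIC improves
  fq <- fake_fit(100, -0.0295, 0.0079)
  expect_identical(strip(selectQuadratic(fl, fq)), fq)
  expect_true(attr(selectQuadratic(fl, fq), "selection")$quadratic_chosen)
  # non-significant quadratic term: linear wins regardless of AIC
  fq2 <- fake_fit(90, -0.0005, 0.0064)  # CI approx [-0.013, 0.012]
  expect_identical(strip(selectQuadratic(fl, fq2)), fl)
  # equal AIC: strict inequality keeps the linear model
  fq3 <- fake_fit(110, -0.0295, 0.0079)
  expect_identical(strip(selectQuadratic(fl, fq3)), fl)
  # guards
  expect_error(selectQuadratic(fl, fake_fit(100, -0.03, 0.005,
                                            fp = c(n = 11, sum_b = 1,
                                                   sum_b2 = 1))),
               "identical data")
  expect_error(selectQuadratic(fl, fake_fit(100, -0.03, 0.005,
                                            converged = FALSE)),
               "converged")
})

test_that("extreme-value trimming removes only strict quantile exceedances", {
  s <- data.frame(b = 1:40)
  expect_equal(nrow(trimExtremes(s, 0.025)), 38L)
  expect_identical(trimExtremes(s, 0), s)
  s2 <- data.frame(b = rep(5, 20))
  expect_equal(nrow(trimExtremes(s2, 0.025)), 20L)
})

test_that("linear predictor sums only the terms a model carries", {
  expect_equal(linearPredictor(10), 10)
  expect_equal(linearPredictor(10.315, coefs = c(tit = 0.025),
                               covariates = c(tit = 1)), 10.34)
  # a supplied quadratic covariate is ignored when the coefficient is absent
  expect_equal(linearPredictor(10.315, coefs = c(tit = 0.025),
                               covariates = c(tit = 1, tit2 = 3)), 10.34)
  expect_equal(linearPredictor(1, omega = 0.5, epsilon = -0.2), 1.3)
})

fake_quad_fit <- function(cov_diag) {
  lay <- indibird:::thetaLayout(2, c("tit", "tit2"), FALSE)
  theta <- stats::setNames(numeric(lay$n), lay$names)
  theta[c("beta_1", "beta_2")] <- c(10, 10.1)
  theta["gamma_tit"] <- 0.2
  theta["gamma_tit2"] <- -0.03
  V <- diag(cov_diag, lay$n)
  dimnames(V) <- list(lay$names, lay$names)
  list(theta = theta, lay = lay, years = c(2001, 2002), fixed_cov = V,
       transforms = list(tit2 = c(mean = 1, sd = 1)))
}

test_that("response-curve bands are seeded, collapse without uncertainty, and widen with curvature variance", {
  fit0 <- fake_quad_fit(0)
  rc0 <- responseCurve(fit0, tit_grid = c(-1, 0, 1), n_draws = 200, seed = 3)
  expect_equal(rc0$lo, rc0$fit, tolerance = 1e-12)
  expect_equal(rc0$hi, rc0$fit, tolerance = 1e-12)
  fit1 <- fake_quad_fit(1e-4)
  rc1 <- responseCurve(fit1, n_draws = 500, seed = 7)
  rc2 <- responseCurve(fit1, n_draws = 500, seed = 7)
  expect_identical(rc1, rc2)
  # with var(gamma2) > 0 the band is wider far from the center:
  # sd of the predictor at grid g includes 1e-4 * ((g^2-1))^2
  w <- rc1$hi - rc1$lo
  g <- rc1$tit
  expect_gt(w[which.min(abs(g - 2.4))], w[which.min(abs(g))])
  sd_an <- sqrt(1e-4 * (1 + g^2 + (g^2 - 1)^2))
  expect_equal(w, 2 * 1.959964 * sd_an, tolerance = 0.15)
})
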