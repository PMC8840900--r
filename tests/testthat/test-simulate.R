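test_that("field simulation honors degenerate limits and the seed", {
  mesh <- buildKnotMesh(cbind(runif(5, 0, 10), runif(5, 0, 10)), 5)
  f0 <- simulateFields(mesh, sigma_omega2 = 0, sigma_eps2 = 0.2,
                       rho_eps = 0.5, kappa = 0.3, n_years = 4, seed = 1)
  expect_equal(f0$omega, rep(0, 5))
  f1 <- simulateFields(mesh, 0.4, 0.2, 0.5, 0.3, n_years = 4, seed = 2)
  f2 <- simulateFields(mesh, 0.4, 0.2, 0.5, 0.3, n_years = 4, seed = 2)
  expect_identical(f1, f2)
})

test_that("simulated spatial fields have the requested covariance", {
  set.seed(41)
  mesh <- buildKnotMesh(cbind(runif(5, 0, 10), runif(5, 0, 10)), 5)
  R <- maternCorrelation(mesh$knots, log(0.3))
  draws <- t(vapply(1:4000, function(i)
    simulateFields(mesh, 0.5, 0.1, 0, 0.3, n_years = 1, seed = 10000 + i)$omega,
    numeric(5)))
  expect_equal(cov(draws), 0.5 * R, tolerance = 0.08, ignore_attr = TRUE)
})

test_that("the spatio-temporal chain is stationary AR(1)", {
  mesh1 <- buildKnotMesh(cbind(0, 0), 1)
  rho <- 0.6; se2 <- 0.3
  f <- simulateFields(mesh1, 1e-12, se2, rho, 1, n_years = 20000, seed = 3)
  e <- as.numeric(f$epsilon)
  expect_equal(cor(e[-1], e[-length(e)]), rho, tolerance = 0.03)
  expect_equal(var(e), se2 / (1 - rho^2), tolerance = 0.05)
  # zero correlation decouples years
  f0 <- simulateFields(mesh1, 1e-12, se2, 0, 1, n_years = 20000, seed = 4)
  e0 <- as.numeric(f0$epsilon)
  expect_lt(abs(cor(e0[-1], e0[-length(e0)])), 0.03)
})

test_that("observation draws are reproducible with the configured moments", {
  cfg <- simConfig(n_sites = 60, n_years = 8, seed = 44)
  s1 <- simulateObservations(cfg)
  s2 <- simulateObservations(cfg)
  expect_identical(s1$samples, s2$samples)
  # mean biomass tracks area * density
  mu <- cfg$area * as.numeric(s1$truth$d)
  expect_equal(mean(s1$samples$b / mu), 1,
               tolerance = 3 * sqrt(cfg$sigma_m2 / nrow(s1$samples)))
  # noiseless limit: b collapses onto area * d within 1%
  cfg0 <- simConfig(n_sites = 30, n_years = 3, sigma_m2 = 1e-6, seed = 45)
  s0 <- simulateObservations(cfg0)
  mu0 <- cfg0$area * as.numeric(s0$truth$d)
  expect_true(all(abs(s0$samples$b / mu0 - 1) < 0.01))
})

test_that("community counts carry the configured biomass structure", {
  cfg <- simConfig(n_sites = 40, n_years = 4, n_forest_species = 1L,
                   n_tit_species = 1L, seed = 46)
  sim <- simulateObservations(cfg)
  com <- simulateCommunity(sim)
  # ingesting the community reproduces the direct biomass in expectation
  rec <- applyGuildFilters(as_point_counts(com$records), com$traits)
  s <- buildSamples(rec, com$traits, com$locations, area = cfg$area)
  # a single forest species makes every response an exact multiple of its mass
  mass <- com$traits$body_mass[com$traits$species_code == "FOR01"]
  expect_true(all(abs(s$b / mass - round(s$b / mass)) < 1e-9))
  key <- paste(sim$samples$point_id, sim$samples$year)
  mu <- cfg$area * as.numeric(sim$truth$d)
  m <- match(paste(s$point_id, s$year), key)
  expect_equal(mean(s$b) / mean(mu[m]), 1, tolerance = 0.1)
  expect_equal(mean(s$tit) / mean(sim$samples$tit[m]), 1, tolerance = 0.1)
  # vanishing density produces an empty forest layer
  cfgz <- simConfig(n_sites = 10, n_years = 2, beta = -15, seed = 47,
                    tit_mean = 1e-6)
  comz <- simulateCommunity(simulateObservations(cfgz))
  expect_equal(sum(grepl("^(FOR|TIT)", comz$records$species_code)), 0L)
})

test_that("fitting ingested community data matches fitting the direct samples", {
  cfg <- simConfig(n_sites = 40, n_years = 6, gamma = c(tit = 0.198),
                   n_forest_species = 25L, seed = 48)
  sim <- simulateObservations(cfg)
  com <- simulateCommunity(sim)
  rec <- applyGuildFilters(as_point_counts(com$records), com$traits)
  s_ing <- buildSamples(rec, com$traits, com$locations, area = cfg$area)
  s_ing <- merge(s_ing, sim$samples[, c("point_id", "year", "pc")],
                 by = c("point_id", "year"))
  spec <- sgmSpec(include_quadratic = FALSE, include_pc = FALSE)
  f_dir <- fitSGM(sim$samples, spec = spec, seed = 48)
  f_ing <- suppressMessages(fitSGM(s_ing, spec = spec, seed = 48))
  expect_true(f_dir$converged && f_ing$converged)
  j <- match("gamma_tit", f_dir$lay$names)
  se_comb <- sqrt(f_dir$se_theta[j]^2 + f_ing$se_theta[j]^2)
  expect_lt(abs(f_dir$theta[j] - f_ing$theta[j]), 3 * se_comb + 0.05)
})

test_that("simulation configs validate their parameters", {
  expect_error(simConfig(), "seed")
  expect_error(simConfig(rho_eps = 1, seed = 1), "abs")
  expect_error(simConfig(sigma_m2 = 0, seed = 1), "sigma_m2")
})

test_that("a two-replicate recovery run completes and reports all parameters", {
  cfg <- simConfig(n_sites = 40, n_years = 6, seed = 49)
  rec <- recoveryExperiment(cfg, n_reps = 2, seed = 49)
  expect_s3_class(rec, "sgm_recovery")
  expect_true(all(c("gamma_tit", "gamma_tit2", "gamma_pc", "sigma_omega",
                    "sigma_eps", "rho_eps") %in% rec$summary$parameter))
  expect_true(all(rec$summary$n + rec$n_failed <= 2))
  expect_output(print(rec), "recovery")
})
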