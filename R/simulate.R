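# Synthetic surveys with the model's exact statistical structure: Matern
# spatial field, AR(1) spatio-temporal field, standardized covariates with
# linear/quadratic effects, gamma (or lognormal) biomass observations, and
# an optional multispecies count layer for the control-group procedure.

#' Simulation configuration
#'
#' Defaults mirror the scale of a single-country breeding-bird analysis:
#' 13 survey years, intercept near 10.25 log(g/km^2), a positive linear and
#' small negative quadratic indicator effect, spatial variance clearly
#' larger than spatio-temporal variance, and a gamma observation layer with
#' a moderate coefficient of variation.
#'
#' @param n_sites number of survey points (one sample per point and year).
#' @param n_years number of consecutive survey years.
#' @param n_knots knots for the fitted mesh; `NULL` = one per point.
#' @param beta intercept(s), recycled to `n_years` (log g/km^2).
#' @param gamma named vector of covariate effects on the standardized scale;
#'   names among `tit`, `tit2`, `pc`, `control`.
#' @param sigma_m2 observation dispersion.
#' @param kappa Matern decorrelation parameter (1/km).
#' @param aniso length-2 anisotropy parameters (0,0 = isotropic).
#' @param rho_eps AR(1) correlation of the spatio-temporal field.
#' @param sigma_omega2,sigma_eps2 field variances.
#' @param area sampled area (km^2).
#' @param domain side length of the square study region (km).
#' @param family,sigma_param,init observation/covariance options as in
#'   [sgmSpec()].
#' @param tit_shape,tit_mean gamma shape and mean (g) of raw titmouse
#'   biomass per sample.
#' @param n_forest_species,n_tit_species community-layer sizes.
#' @param seed mandatory integer seed.
#' @return an object of class `sim_config`.
#' @export
simConfig <- function(n_sites = 100L, n_years = 13L, n_knots = NULL,
                      beta = 10.25,
                      gamma = c(tit = 0.198, tit2 = -0.030, pc = -0.019),
                      sigma_m2 = 0.5, kappa = 0.1, aniso = c(0, 0),
                      rho_eps = 0.5, sigma_omega2 = 0.411,
                      sigma_eps2 = 0.087, area = 0.031, domain = 100,
                      family = "gamma", sigma_param = "cv",
                      init = "stationary",
                      tit_shape = 1.5, tit_mean = 30,
                      n_forest_species = 30L, n_tit_species = 6L,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation", call. = FALSE)
  stopifnot(sigma_m2 > 0, sigma_omega2 > 0, sigma_eps2 > 0,
            abs(rho_eps) < 1, kappa > 0, n_years >= 1L, n_sites >= 1L)
  structure(list(n_sites = as.integer(n_sites),
                 n_years = as.integer(n_years), n_knots = n_knots,
                 beta = rep_len(beta, n_years), gamma = gamma,
                 sigma_m2 = sigma_m2, kappa = kappa, aniso = aniso,
                 rho_eps = rho_eps, sigma_omega2 = sigma_omega2,
                 sigma_eps2 = sigma_eps2, area = area, domain = domain,
                 family = family, sigma_param = sigma_param, init = init,
                 tit_shape = tit_shape, tit_mean = tit_mean,
                 n_forest_species = as.integer(n_forest_species),
                 n_tit_species = as.integer(n_tit_species),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the spatial and spatio-temporal random fields
#'
#' `omega ~ MVN(0, sigma_omega2 R)` by Cholesky factorization; the first
#' year of `eps` from its stationary law (or unit variance under
#' `init = "unit"`), later years by the AR(1) recursion with innovation
#' covariance `sigma_eps2 R`.
#'
#' @param mesh a [buildKnotMesh()] mesh.
#' @param sigma_omega2,sigma_eps2,rho_eps,kappa,aniso,n_years,init model
#'   parameters as in [simConfig()].
#' @param seed integer seed.
#' @return list with `omega` (vector) and `epsilon` (knots-by-years matrix).
#' @export
simulateFields <- function(mesh, sigma_omega2, sigma_eps2, rho_eps, kappa,
                           aniso = NULL, n_years, seed,
                           init = c("stationary", "unit")) {
  init <- match.arg(init)
  R <- maternCorrelation(mesh$knots, log(kappa), aniso)
  L <- t(tryCatch(chol(R), error = function(e) {
    stop("spatial correlation factorization failed at kappa = ", kappa,
         call. = FALSE)
  }))
  x <- mesh$n_knots
  set.seed(seed)
  omega <- sqrt(sigma_omega2) * drop(L %*% stats::rnorm(x))
  eps <- matrix(0, x, n_years)
  v1 <- if (init == "stationary") sigma_eps2 / (1 - rho_eps^2) else 1
  eps[, 1L] <- sqrt(v1) * drop(L %*% stats::rnorm(x))
  if (n_years > 1L) {
    for (t in 2:n_years) {
      eps[, t] <- rho_eps * eps[, t - 1L] +
        sqrt(sigma_eps2) * drop(L %*% stats::rnorm(x))
    }
  }
  list(omega = omega, epsilon = eps)
}

simStdCovariates <- function(config, n) {
  tit_raw <- stats::rgamma(n, shape = config$tit_shape,
                           scale = config$tit_mean / config$tit_shape)
  pc <- stats::rnorm(n)
  control_raw <- stats::rgamma(n, shape = config$tit_shape,
                               scale = config$tit_mean / config$tit_shape)
  tit_std <- (tit_raw - mean(tit_raw)) / stats::sd(tit_raw)
  sq <- tit_std^2
  tit2_std <- (sq - mean(sq)) / stats::sd(sq)
  pc_std <- (pc - mean(pc)) / stats::sd(pc)
  list(tit_raw = tit_raw, tit = tit_std, tit2 = tit2_std,
       pc_raw = pc, pc = pc_std,
       control_raw = control_raw,
       control = (control_raw - mean(control_raw)) / stats::sd(control_raw))
}

gammaTerm <- function(gamma, name, value) {
  if (!is.null(gamma) && name %in% names(gamma)) gamma[[name]] * value else 0
}

#' Simulate biomass samples from the model
#'
#' Draws point locations uniformly on the square domain, the random fields
#' from [simulateFields()], iid raw titmouse biomass and productivity
#' scores (standardized before entering the predictor, as in fitting), and
#' observed biomass from the configured observation family with mean
#' `area * d(s,t)`.  The realized parameters and fields are returned as the
#' truth for recovery checks.
#'
#' @param config a [simConfig()].
#' @param seed optional override of `config$seed`.
#' @return list of class `sgm_sim` with `samples` (data.frame: `site_id`,
#'   `point_id`, `year`, `x`, `y`, `b`, `tit`, `pc`, `area`), `mesh`,
#'   `truth` (fixed effects, fields, standardized covariates) and `config`.
#' @export
simulateObservations <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_sites
  coords <- cbind(x = stats::runif(n, 0, config$domain),
                  y = stats::runif(n, 0, config$domain))
  mesh <- buildKnotMesh(coords,
                        if (is.null(config$n_knots)) n else config$n_knots,
                        seed = seed)
  fields <- simulateFields(mesh, config$sigma_omega2, config$sigma_eps2,
                           config$rho_eps, config$kappa,
                           if (any(config$aniso != 0)) config$aniso else NULL,
                           config$n_years, seed = seed + 1L,
                           init = config$init)
  knot <- mapToKnots(coords, mesh)
  Tn <- config$n_years
  idx <- expand.grid(site = seq_len(n), t = seq_len(Tn))
  set.seed(seed + 2L)
  cv <- simStdCovariates(config, nrow(idx))
  ell <- config$beta[idx$t] + fields$omega[knot[idx$site]] +
    fields$epsilon[cbind(knot[idx$site], idx$t)] +
    gammaTerm(config$gamma, "tit", cv$tit) +
    gammaTerm(config$gamma, "tit2", cv$tit2) +
    gammaTerm(config$gamma, "pc", cv$pc) +
    gammaTerm(config$gamma, "control", cv$control)
  d <- exp(ell)
  b <- obsFamilyDraw(nrow(idx), config$area * d, config$sigma_m2,
                     config$family, config$sigma_param)
  samples <- data.frame(
    site_id = sprintf("S%03d", idx$site),
    point_id = sprintf("P%03d", idx$site),
    year = 2000L + idx$t,
    x = coords[idx$site, 1L], y = coords[idx$site, 2L],
    b = b, tit = cv$tit_raw, pc = cv$pc_raw, control = cv$control_raw,
    area = config$area)
  structure(list(samples = samples, mesh = mesh,
                 truth = list(beta = config$beta, gamma = config$gamma,
                              sigma_m2 = config$sigma_m2,
                              kappa = config$kappa, rho_eps = config$rho_eps,
                              sigma_omega2 = config$sigma_omega2,
                              sigma_eps2 = config$sigma_eps2,
                              fields = fields, knot = knot,
                              d = matrix(d, n, Tn), tit_std = cv$tit,
                              pc_std = cv$pc),
                 config = config, seed = seed),
            class = "sgm_sim")
}

#' Simulate a multispecies point-count layer
#'
#' Converts the simulated expected biomass into species-level counts so the
#' full ingestion pipeline can run on synthetic data.  Non-titmouse forest
#' species `k` receives Poisson counts with intensity
#' `weight_k * area * d(s,t) / mass_k`, so the summed biomass has
#' expectation `area * d(s,t)`; titmouse species are driven by the
#' simulated raw titmouse biomass in the same way.  A non-forest wader
#' species with habitat-independent counts is included to exercise the
#' guild filters.
#'
#' @param sim an `sgm_sim` from [simulateObservations()].
#' @param seed integer seed for the count draws.
#' @return list with `records` (one row per species count, in
#'   individual-count mode), `traits` (species trait table) and `locations`
#'   (point coordinates).
#' @export
simulateCommunity <- function(sim, seed = sim$seed + 10L) {
  config <- sim$config
  nf <- config$n_forest_species
  nt <- config$n_tit_species
  set.seed(seed)
  traits <- data.frame(
    species_code = c(sprintf("FOR%02d", seq_len(nf)),
                     sprintf("TIT%02d", seq_len(nt)), "WAD01"),
    body_mass = c(round(stats::rlnorm(nf, log(25), 0.6), 1),
                  round(stats::runif(nt, 9, 20), 1), 150),
    is_titmouse = c(rep(FALSE, nf), rep(TRUE, nt), FALSE),
    is_excluded_guild = c(rep(FALSE, nf + nt), TRUE),
    is_forest = c(rep(TRUE, nf + nt), FALSE))
  w_f <- stats::rgamma(nf, 1); w_f <- w_f / sum(w_f)
  w_t <- stats::rgamma(nt, 1); w_t <- w_t / sum(w_t)
  s <- sim$samples
  n <- nrow(s)
  mk <- function(codes, weights, target) {
    lam <- outer(target, weights) /
      rep(traits$body_mass[match(codes, traits$species_code)], each = n)
    cnt <- matrix(stats::rpois(length(lam), lam), n)
    ij <- which(cnt > 0, arr.ind = TRUE)
    if (nrow(ij) == 0L) {
      return(data.frame(site_id = character(0), point_id = character(0),
                        year = integer(0), period = integer(0),
                        species_code = character(0), count = integer(0),
                        habitat_code = character(0)))
    }
    data.frame(site_id = s$site_id[ij[, 1L]], point_id = s$point_id[ij[, 1L]],
               year = s$year[ij[, 1L]], period = 1L,
               species_code = codes[ij[, 2L]], count = cnt[ij],
               habitat_code = "forest")
  }
  expected_b <- s$area * sim$truth$d[cbind(
    match(s$point_id, unique(s$point_id)), s$year - min(s$year) + 1L)]
  rec <- rbind(
    mk(traits$species_code[seq_len(nf)], w_f, expected_b),
    mk(traits$species_code[nf + seq_len(nt)], w_t, s$tit),
    mk("WAD01", 1, rep(2 * 150 * 0.02, n)))
  rec <- rec[order(rec$site_id, rec$point_id, rec$year, rec$species_code), ]
  rownames(rec) <- NULL
  locations <- unique(data.frame(site_id = s$site_id, point_id = s$point_id,
                                 x = s$x, y = s$y))
  list(records = rec, traits = traits, locations = locations,
       mode = "individual_counts")
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates from a configuration and refits the model,
#' aggregating bias, root-mean-square error and 95% CI coverage for the
#' covariate effects and covariance parameters.  Replicates whose fits do
#' not converge are recorded and excluded from the aggregates.
#'
#' @param config a [simConfig()].
#' @param n_reps number of replicates (>= 2).
#' @param seed integer; replicate r uses `seed + r` for simulation.
#' @param spec fitted-model specification; defaults to one matching the
#'   generating covariate structure.
#' @param fit_control passed to [fitSGM()] `control`.
#' @return list of class `sgm_recovery`: `summary` (data.frame with
#'   `parameter`, `truth`, `bias`, `rmse`, `coverage`, `n`), `estimates`
#'   (per-replicate long table) and `n_failed`.
#' @export
recoveryExperiment <- function(config, n_reps, seed = config$seed,
                               spec = NULL, fit_control = list()) {
  stopifnot(n_reps >= 2)
  if (is.null(spec)) {
    spec <- sgmSpec(indicator = "tit",
                    include_quadratic = "tit2" %in% names(config$gamma),
                    include_pc = "pc" %in% names(config$gamma),
                    family = config$family, sigma_param = config$sigma_param,
                    n_knots = config$n_knots, area = config$area,
                    init = config$init)
  }
  truth <- c(gamma_tit = unname(config$gamma["tit"]),
             gamma_tit2 = if ("tit2" %in% names(config$gamma))
               unname(config$gamma["tit2"]),
             gamma_pc = if ("pc" %in% names(config$gamma))
               unname(config$gamma["pc"]),
             sigma_omega = sqrt(config$sigma_omega2),
             sigma_eps = sqrt(config$sigma_eps2),
             rho_eps = config$rho_eps)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulateObservations(config, seed = seed + r)
    fit <- tryCatch(
      fitSGM(sim$samples, spec = spec, seed = seed + r,
             control = fit_control),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    fe <- fixedEffects(fit)
    fe <- fe[fe$term %in% names(truth), ]
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r, parameter = fe$term, estimate = fe$estimate, se = fe$se,
      lo = fe$lo, hi = fe$hi,
      truth = unname(truth[fe$term]),
      covered = fe$lo <= unname(truth[fe$term]) &
        unname(truth[fe$term]) <= fe$hi)
  }
  est <- do.call(rbind, rows)
  if (is.null(est)) {
    return(structure(list(summary = data.frame(), estimates = est,
                          n_failed = n_failed, n_reps = n_reps,
                          config = config, seed = seed),
                     class = "sgm_recovery"))
  }
  summary <- do.call(rbind, lapply(split(est, est$parameter), function(d) {
    data.frame(parameter = d$parameter[1L], truth = d$truth[1L],
               bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$covered, na.rm = TRUE), n = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = est, n_failed = n_failed,
                 n_reps = n_reps, config = config, seed = seed),
            class = "sgm_recovery")
}

#' @export
print.sgm_recovery <- function(x, ...) {
  cat("Parameter recovery over", x$n_reps, "replicates (",
      x$n_failed, "failed )\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
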