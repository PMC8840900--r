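# Model fitting: outer quasi-Newton maximization of the Laplace marginal
# likelihood, empirical-Bayes random fields, delta-method standard errors.

z95 <- 1.959964

# ---- covariate preparation -------------------------------------------------

# Standardize the model covariates (pooled over all rows, before any
# zero-biomass removal).  The squared indicator covariate is the
# standardized square of the standardized biomass, so both enter on an
# SD scale.  Returns the design matrix plus the transforms needed to map a
# standardized-titmouse grid back onto the quadratic column.
prepareCovariates <- function(samples, spec) {
  need <- setdiff(spec$covariates, "tit2")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("samples lack covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- matrix(0, nrow(samples), length(spec$covariates),
              dimnames = list(NULL, spec$covariates))
  transforms <- list()
  for (cv in spec$covariates) {
    if (cv == "tit2") next
    v <- samples[[cv]]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("covariate '", cv, "' has zero variance; cannot standardize",
           call. = FALSE)
    }
    X[, cv] <- (v - m) / s
    transforms[[cv]] <- c(mean = m, sd = s)
  }
  if ("tit2" %in% spec$covariates) {
    sq <- X[, "tit"]^2
    m2 <- mean(sq); s2 <- stats::sd(sq)
    X[, "tit2"] <- (sq - m2) / s2
    transforms[["tit2"]] <- c(mean = m2, sd = s2)
  }
  list(X = X, transforms = transforms)
}

# ---- natural-scale parameter mapping ---------------------------------------

thetaToFixed <- function(theta, lay, years) {
  cp <- thetaCovParams(theta, lay)
  gamma <- theta[lay$i_gamma]
  names(gamma) <- sub("^gamma_", "", lay$names[lay$i_gamma])
  list(beta = stats::setNames(theta[lay$i_beta], years),
       gamma = gamma,
       sigma_m2 = exp(theta[[lay$i_logv]]),
       kappa = exp(cp$log_kappa),
       aniso = cp$aniso,
       rho_eps = cp$rho,
       sigma_omega2 = cp$sigma_omega2,
       sigma_eps2 = cp$sigma_eps2)
}

fixedToTheta <- function(fixed, lay) {
  th <- numeric(lay$n)
  th[lay$i_beta] <- fixed$beta
  if (length(lay$i_gamma)) {
    nm <- sub("^gamma_", "", lay$names[lay$i_gamma])
    g <- fixed$gamma[nm]
    g[is.na(g)] <- 0
    th[lay$i_gamma] <- g
  }
  th[lay$i_logv] <- log(fixed$sigma_m2)
  th[lay$i_R[1L]] <- log(fixed$kappa)
  if (length(lay$i_R) == 3L) th[lay$i_R[2:3]] <- fixed$aniso
  th[lay$i_C] <- c(atanh(fixed$rho_eps), log(fixed$sigma_omega2),
                   log(fixed$sigma_eps2))
  names(th) <- lay$names
  th
}

defaultStart <- function(data, lay) {
  bpos <- pmax(data$b, min(data$b[data$b > 0]))
  beta0 <- vapply(seq_len(data$n_years), function(t) {
    log(mean(bpos[data$year_idx == t]) / data$a)
  }, numeric(1))
  dpos <- data$distm[data$distm > 0]
  kappa0 <- if (length(dpos)) 2 / stats::median(dpos) else 1
  fixedToTheta(list(beta = beta0, gamma = numeric(0), sigma_m2 = 0.5,
                    kappa = kappa0, aniso = c(0, 0), rho_eps = 0.3,
                    sigma_omega2 = 0.3, sigma_eps2 = 0.2), lay)
}

# ---- main fitting routine --------------------------------------------------

#' Fit the spatial Gompertz model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the fixed
#' effects (per-year intercepts, covariate coefficients, observation
#' dispersion, Matern decorrelation, AR(1) correlation and the two field
#' variances) with analytic gradients; recovers the spatial and
#' spatio-temporal fields at their conditional modes (empirical Bayes) and
#' reports delta-method standard errors, Wald 95% intervals and AIC.
#'
#' Covariates are standardized internally (pooled over all supplied rows,
#' before zero-biomass samples are dropped); the squared titmouse term is
#' the standardized square of the standardized biomass.
#'
#' @param samples data.frame with columns `b` (biomass, g), `x`, `y`
#'   (planar km), `year`, and the covariate columns the spec requires
#'   (`tit`, and optionally `pc`, `control`).
#' @param spec an [sgmSpec()].
#' @param mesh optional [buildKnotMesh()] result; built from the sample
#'   locations otherwise.
#' @param start optional named list of natural-scale starting values
#'   (`beta`, `gamma`, `sigma_m2`, `kappa`, `rho_eps`, `sigma_omega2`,
#'   `sigma_eps2`).
#' @param seed integer; seeds the mesh clustering and the jittered restarts.
#' @param control list; `inner_tol` (default 1e-8), `outer_tol` (relative
#'   gradient max-norm declaring convergence, default 1e-4), `max_restarts`
#'   (default 3), `iter_max` (default 400), `se` (compute the outer Hessian
#'   and standard errors, default TRUE), `scale_base` (nlminb scale, default
#'   4; intercepts get twice this).
#' @return an object of class `sgm_fit`; see [fixedEffects()].
#' @export
fitSGM <- function(samples, spec = sgmSpec(), mesh = NULL, start = NULL,
                   seed = 1L, control = list()) {
  ctrl <- utils::modifyList(
    list(inner_tol = 1e-8, outer_tol = 1e-4, max_restarts = 3L,
         iter_max = 400L, se = TRUE, scale_base = 4),
    control)
  stopifnot(is.data.frame(samples),
            all(c("b", "x", "y", "year") %in% names(samples)))
  if (any(samples$b < 0)) stop("negative biomass in samples", call. = FALSE)
  years <- sort(unique(samples$year))
  if (length(years) < 2L) {
    stop("at least 2 years of data are required", call. = FALSE)
  }

  cov <- prepareCovariates(samples, spec)
  keep <- samples$b > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " zero-biomass sample(s) (",
            signif(100 * n_dropped / nrow(samples), 3), "% of ",
            nrow(samples), ")")
  }
  samples2 <- samples[keep, , drop = FALSE]
  X <- cov$X[keep, , drop = FALSE]

  coords <- as.matrix(samples2[, c("x", "y")])
  if (is.null(mesh)) {
    x_req <- if (is.null(spec$n_knots)) nrow(unique(coords)) else spec$n_knots
    mesh <- buildKnotMesh(coords, x_req, seed = seed)
  }
  knot <- mapToKnots(coords, mesh)
  year_idx <- match(samples2$year, years)

  data <- sgmData(b = samples2$b, knot = knot, year_idx = year_idx, X = X,
                  a = spec$area, mesh = mesh, n_years = length(years),
                  family = spec$family, sigma_param = spec$sigma_param,
                  init = spec$init, aniso = spec$anisotropy)
  lay <- thetaLayout(length(years), spec$covariates, spec$anisotropy)
  obj <- makeLaplaceObjective(data, lay, inner_tol = ctrl$inner_tol)

  th0 <- if (is.null(start)) defaultStart(data, lay) else fixedToTheta(start, lay)

  # outer quasi-Newton; convergence is declared from the relative gradient
  # max-norm, not nlminb's own stopping codes.  The scale vector speeds up
  # nlminb's model building considerably on this objective (intercepts live
  # on a different scale than the log-variance parameters).
  scl <- rep(ctrl$scale_base, lay$n)
  scl[lay$i_beta] <- 2 * ctrl$scale_base
  run_opt <- function(th) {
    iters <- 0L
    passes <- 0L
    repeat {
      opt <- stats::nlminb(th, obj$fn, obj$gr, scale = scl,
                           control = list(iter.max = ctrl$iter_max,
                                          eval.max = 2L * ctrl$iter_max,
                                          rel.tol = 1e-8))
      iters <- iters + opt$iterations
      th <- opt$par
      passes <- passes + 1L
      g <- tryCatch(obj$gr(th), error = function(e) rep(NA_real_, lay$n))
      rel_g <- max(abs(g)) / max(1, abs(opt$objective))
      done <- is.finite(rel_g) && rel_g < ctrl$outer_tol
      if (done || passes >= 2L || iters >= ctrl$iter_max) break
    }
    list(opt = opt, grad = g, rel_g = rel_g,
         ok = is.finite(rel_g) && rel_g < ctrl$outer_tol)
  }

  res <- run_opt(th0)
  tries <- 0L
  best <- res
  while (!res$ok && tries < ctrl$max_restarts) {
    tries <- tries + 1L
    set.seed(seed + 1000L * tries)
    jit <- stats::rnorm(lay$n, 0, ifelse(lay$type %in% c("R", "C"), 0.5, 0.2))
    res <- run_opt(th0 + jit)
    if (res$ok || res$opt$objective < best$opt$objective) best <- res
  }
  if (!res$ok) res <- best

  theta <- res$opt$par
  names(theta) <- lay$names
  nll <- res$opt$objective
  st <- obj$state(theta)
  converged <- res$ok && st$inner$converged

  # Variance-type parameters can run to the boundary of the parameter space
  # (a field variance collapsing to zero on weakly informative data); those
  # directions are flat, so they are excluded from the curvature check and
  # reported without standard errors rather than failing the whole fit.
  boundary <- (grepl("^log_sigma", lay$names) & theta < -13) |
    (lay$names == "rho_t" & abs(tanh(theta)) > 0.999)
  # a vanished spatio-temporal variance leaves its AR(1) correlation flat
  if (boundary[match("log_sigma_eps2", lay$names)]) {
    boundary[match("rho_t", lay$names)] <- TRUE
  }
  if (any(boundary)) {
    message("parameter(s) at the boundary: ",
            paste(lay$names[boundary], collapse = ", "))
  }

  # outer Hessian via forward differences of the analytic gradient
  se_th <- rep(NA_real_, lay$n)
  fixed_cov <- NULL
  hess_pd <- NA
  if (ctrl$se) {
    hstep <- 1e-4 * pmax(1, abs(theta))
    g0 <- res$grad
    Hout <- matrix(NA_real_, lay$n, lay$n)
    for (j in seq_len(lay$n)) {
      thj <- theta; thj[j] <- thj[j] + hstep[j]
      Hout[, j] <- (obj$gr(thj) - g0) / hstep[j]
    }
    Hout <- (Hout + t(Hout)) / 2
    sub <- which(!boundary)
    ch <- tryCatch(chol(Hout[sub, sub, drop = FALSE]),
                   error = function(e) NULL)
    hess_pd <- !is.null(ch)
    fixed_cov <- matrix(NA_real_, lay$n, lay$n,
                        dimnames = list(lay$names, lay$names))
    if (hess_pd) {
      fixed_cov[sub, sub] <- chol2inv(ch)
    } else {
      ev <- eigen(Hout[sub, sub, drop = FALSE], symmetric = TRUE)
      pos <- pmax(ev$values, 1e-10 * max(abs(ev$values)))
      fixed_cov[sub, sub] <- ev$vectors %*% ((1 / pos) * t(ev$vectors))
    }
    se_th[sub] <- sqrt(pmax(diag(fixed_cov)[sub], 0))
    converged <- converged && hess_pd
  }

  # empirical-Bayes field split: omega | eta is Gaussian with weights
  # sigma_omega2 * C^{-1} 1 across years
  cp <- thetaCovParams(theta, lay)
  Emat <- matrix(st$inner$eta, data$n_knots, data$n_years)
  w_omega <- cp$sigma_omega2 * rowSums(st$prep$Cinv)
  omega <- drop(Emat %*% w_omega)
  eps <- Emat - omega

  # knot-by-year covariate means for predicted density (0 = covariate mean)
  Xcell <- matrix(0, data$n_lat, ncol(X))
  if (ncol(X) > 0 && nrow(X) > 0) {
    sums <- rowsum(X, data$cell)
    cnts <- as.vector(rowsum(rep(1, nrow(X)), data$cell))
    Xcell[as.integer(rownames(sums)), ] <- sums / cnts
  }
  beta <- theta[lay$i_beta]
  gamma <- theta[lay$i_gamma]
  eta_cell <- as.vector(Emat)
  covpart <- if (length(gamma)) drop(Xcell %*% gamma) else 0
  d_hat <- matrix(exp(rep(beta, each = data$n_knots) + eta_cell + covpart),
                  data$n_knots, data$n_years,
                  dimnames = list(NULL, years))

  fit <- structure(list(
    spec = spec, mesh = mesh, years = years, lay = lay,
    theta = theta, se_theta = stats::setNames(se_th, lay$names),
    fixed = thetaToFixed(theta, lay, years),
    fixed_cov = fixed_cov,
    nll = nll, aic = 2 * lay$n + 2 * nll,
    n_fixed = lay$n,
    converged = converged, hessian_pd = hess_pd,
    boundary = lay$names[boundary],
    grad_rel = res$rel_g, restarts = tries,
    fields = list(omega = omega, epsilon = eps, eta = Emat),
    d_hat = d_hat,
    transforms = cov$transforms,
    n_samples = nrow(samples2), n_dropped = n_dropped,
    data_fingerprint = c(n = nrow(samples2), sum_b = sum(samples2$b),
                         sum_b2 = sum(samples2$b^2)),
    seed = seed
  ), class = "sgm_fit")
  fit
}

#' @export
print.sgm_fit <- function(x, ...) {
  cat("Spatial Gompertz model fit (", x$spec$family, " family)\n", sep = "")
  cat("  samples:", x$n_samples, " knots:", x$mesh$n_knots,
      " years:", length(x$years), "\n")
  cat("  marginal NLL:", format(x$nll, digits = 8),
      " AIC:", format(x$aic, digits = 8), "\n")
  cat("  converged:", x$converged,
      sprintf("(rel. gradient %.2e, %d restart(s))\n", x$grad_rel, x$restarts))
  if (length(x$boundary)) {
    cat("  at boundary:", paste(x$boundary, collapse = ", "), "\n")
  }
  print(fixedEffects(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fixed-effect table on interpretable scales
#'
#' Estimates, standard errors and Wald 95% intervals for the covariate
#' effects and the covariance parameters.  Variance parameters are reported
#' as standard deviations (`sigma_omega`, `sigma_eps`) via the delta method;
#' the AR(1) correlation and the Matern decorrelation parameter are
#' back-transformed likewise.
#'
#' @param fit an `sgm_fit`.
#' @param betas include the per-year intercepts? default FALSE.
#' @return data.frame with columns `term`, `estimate`, `se`, `lo`, `hi`,
#'   `significant`.
#' @export
fixedEffects <- function(fit, betas = FALSE) {
  lay <- fit$lay
  th <- fit$theta
  se <- fit$se_theta
  rows <- list()
  add <- function(term, est, s) {
    sig <- significance(est, s)
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, estimate = est, se = s, lo = sig$ci[1L], hi = sig$ci[2L],
      significant = sig$significant)
  }
  if (betas) {
    for (k in seq_along(lay$i_beta)) {
      add(paste0("beta_", fit$years[k]), th[lay$i_beta[k]], se[lay$i_beta[k]])
    }
  }
  for (k in seq_along(lay$i_gamma)) {
    add(lay$names[lay$i_gamma[k]], th[lay$i_gamma[k]], se[lay$i_gamma[k]])
  }
  # delta method: d exp(t/2)/dt = exp(t/2)/2 ; d tanh / dt = 1 - rho^2
  iC <- lay$i_C
  sw <- exp(th[iC[2L]] / 2); add("sigma_omega", sw, sw / 2 * se[iC[2L]])
  se_ <- exp(th[iC[3L]] / 2); add("sigma_eps", se_, se_ / 2 * se[iC[3L]])
  rho <- tanh(th[iC[1L]]); add("rho_eps", rho, (1 - rho^2) * se[iC[1L]])
  sm <- exp(th[lay$i_logv] / 2); add("sigma_m", sm, sm / 2 * se[lay$i_logv])
  kap <- exp(th[lay$i_R[1L]]); add("kappa", kap, kap * se[lay$i_R[1L]])
  do.call(rbind, rows)
}

#' Wald 95% interval and significance flag
#'
#' The interval is `estimate +/- 1.959964 * se`; the estimate is called
#' significant when zero lies strictly outside the closed interval.
#'
#' @param estimate point estimate.
#' @param se standard error, > 0 (0 gives a degenerate interval).
#' @return list with `ci` (length 2) and `significant`.
#' @examples
#' significance(0.025, 0.0102)  # significant: CI approx [0.005, 0.045]
#' @export
significance <- function(estimate, se) {
  ci <- estimate + c(-1, 1) * z95 * se
  list(ci = ci, significant = isTRUE(ci[1L] > 0 || ci[2L] < 0))
}

#' Choose between the linear and quadratic indicator models
#'
#' The quadratic model is adopted only when it has strictly lower AIC than
#' the linear model and its quadratic coefficient is significant at the 95%
#' level; otherwise inference rests on the linear model.
#'
#' @param fit_linear,fit_quadratic `sgm_fit` objects fitted to identical
#'   data (checked via a data fingerprint).
#' @return the chosen `sgm_fit`, with attribute `"selection"` recording the
#'   AIC difference and the quadratic significance.
#' @export
selectQuadratic <- function(fit_linear, fit_quadratic) {
  if (!isTRUE(all.equal(fit_linear$data_fingerprint,
                        fit_quadratic$data_fingerprint))) {
    stop("the two fits were not produced from identical data", call. = FALSE)
  }
  if (!fit_linear$converged || !fit_quadratic$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  j <- match("gamma_tit2", fit_quadratic$lay$names)
  sig2 <- significance(fit_quadratic$theta[j], fit_quadratic$se_theta[j])
  use_quad <- fit_quadratic$aic < fit_linear$aic && sig2$significant
  out <- if (use_quad) fit_quadratic else fit_linear
  attr(out, "selection") <- list(
    delta_aic = fit_linear$aic - fit_quadratic$aic,
    gamma2 = fit_quadratic$theta[j], gamma2_ci = sig2$ci,
    gamma2_significant = sig2$significant, quadratic_chosen = use_quad)
  out
}

#' Log-linked linear predictor
#'
#' Sum of the intercept, field values and covariate terms on the log-density
#' scale; terms absent from a model simply contribute zero.
#'
#' @param beta year intercept (log g/km^2).
#' @param omega,epsilon field values at the sample's knot (default 0).
#' @param coefs named numeric vector of coefficients (e.g. `c(tit = 0.025)`).
#' @param covariates named numeric vector of standardized covariate values;
#'   names not present in `coefs` are ignored.
#' @return log expected density.
#' @examples
#' linearPredictor(10.315, coefs = c(tit = 0.025), covariates = c(tit = 1))
#' @export
linearPredictor <- function(beta, omega = 0, epsilon = 0,
                            coefs = numeric(), covariates = numeric()) {
  shared <- intersect(names(coefs), names(covariates))
  beta + omega + epsilon + sum(coefs[shared] * covariates[shared])
}

#' Predicted response curve with a sampling-based confidence band
#'
#' Draws the first-year intercept and the titmouse coefficients jointly from
#' their estimated multivariate normal distribution and propagates each draw
#' through the predictor over a grid of standardized titmouse biomass,
#' reporting the 2.5/50/97.5 percentiles of log predicted density.
#'
#' @param fit an `sgm_fit` with an estimated covariance (`control$se`).
#' @param tit_grid grid of standardized titmouse biomass values.
#' @param year which year's intercept to use (default the first).
#' @param n_draws number of multivariate-normal draws.
#' @param seed integer seed.
#' @return data.frame with columns `tit`, `lo`, `median`, `hi`, `fit`.
#' @export
responseCurve <- function(fit, tit_grid = seq(-2.5, 2.5, length.out = 101),
                          year = fit$years[1L], n_draws = 1000L, seed = 1L) {
  if (is.null(fit$fixed_cov)) stop("fit carries no covariance; refit with se")
  lay <- fit$lay
  idx <- c(lay$i_beta[match(year, fit$years)],
           lay$i_gamma[match(c("tit", "tit2"), sub("^gamma_", "",
                                                   lay$names[lay$i_gamma]))])
  idx <- idx[!is.na(idx)]
  mu <- fit$theta[idx]
  Sg <- fit$fixed_cov[idx, idx, drop = FALSE]
  # symmetric square root; tolerates exactly singular covariances
  ev <- eigen((Sg + t(Sg)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1e-300)) {
    stop("fixed-effect covariance is not positive semidefinite",
         call. = FALSE)
  }
  L <- sqrt(pmax(ev$values, 0)) * t(ev$vectors)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * length(mu)), n_draws)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  draws <- sweep(Z %*% L, 2L, mu, "+")
  has_quad <- length(idx) == 3L
  tf <- fit$transforms
  basis <- function(g) {
    c(1, g, if (has_quad) (g^2 - tf$tit2["mean"]) / tf$tit2["sd"])
  }
  out <- t(vapply(tit_grid, function(g) {
    v <- drop(draws %*% basis(g))
    point <- sum(mu * basis(g))
    c(stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE), point)
  }, numeric(4)))
  data.frame(tit = tit_grid, lo = out[, 1L], median = out[, 2L],
             hi = out[, 3L], fit = out[, 4L])
}

#' Remove extreme biomass observations
#'
#' Drops samples whose biomass lies strictly below the lower or strictly
#' above the upper quantile of the response (linear-interpolation
#' quantiles), mirroring a 2.5%-trim sensitivity refit.
#'
#' @param samples data.frame with a `b` column.
#' @param fraction tail fraction removed on each side, in `[0, 0.5)`.
#' @return the trimmed data.frame.
#' @export
trimExtremes <- function(samples, fraction = 0.025) {
  stopifnot(fraction >= 0, fraction < 0.5)
  if (fraction == 0) return(samples)
  q <- stats::quantile(samples$b, c(fraction, 1 - fraction), type = 7,
                       names = FALSE)
  samples[samples$b >= q[1L] & samples$b <= q[2L], , drop = FALSE]
}
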