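# Direct (non-collapsed) joint likelihood and the exported marginal
# likelihood.  jointNLL writes out the model exactly as stated -- the
# observation terms plus the MVN densities of the spatial field and of the
# AR(1) chain of spatio-temporal fields -- and is deliberately independent
# of the Kronecker-collapsed machinery in laplace.R, so the two can be
# cross-checked.

mvnNLLchol <- function(z, cholS) {
  u <- forwardsolve(t(cholS), z)
  0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(cholS))) + sum(u^2))
}

#' Joint negative log-likelihood of data and random fields
#'
#' The unnormalized posterior of the fields: observation negative
#' log-likelihood plus the MVN negative log densities of the spatial field
#' `omega` (covariance `sigma_omega2 * R`), of the first-year
#' spatio-temporal field (stationary AR(1) variance by default, unit
#' variance under `init = "unit"`), and of each subsequent year given
#' `rho_eps` times the previous one with innovation covariance
#' `sigma_eps2 * R`.
#'
#' @param fixed named list of natural-scale fixed effects: `beta` (length
#'   n_years), `gamma` (named vector over the spec's covariates, may be
#'   empty), `sigma_m2`, `kappa`, `aniso` (length 2, optional), `rho_eps`,
#'   `sigma_omega2`, `sigma_eps2`.
#' @param omega numeric vector over knots.
#' @param epsilon matrix, knots by years.
#' @param b observed biomass per sample.
#' @param knot integer knot index per sample.
#' @param year integer year index per sample (1-based).
#' @param X covariate matrix (columns named as in `spec$covariates`), or
#'   NULL when the spec has no covariates.
#' @param mesh a [buildKnotMesh()] mesh.
#' @param spec an [sgmSpec()].
#' @return the joint negative log-likelihood (a single number).
#' @export
jointNLL <- function(fixed, omega, epsilon, b, knot, year, X = NULL,
                     mesh, spec = sgmSpec(indicator = "none",
                                          include_pc = FALSE)) {
  epsilon <- as.matrix(epsilon)
  n_years <- ncol(epsilon)
  stopifnot(length(omega) == mesh$n_knots, nrow(epsilon) == mesh$n_knots)
  R <- maternCorrelation(mesh$knots, log(fixed$kappa),
                         if (spec$anisotropy) fixed$aniso else NULL)
  cholR <- tryCatch(chol(R), error = function(e) {
    stop("spatial correlation matrix is not positive-definite at kappa = ",
         signif(fixed$kappa, 4), call. = FALSE)
  })
  gpart <- if (!is.null(X) && length(fixed$gamma)) {
    drop(as.matrix(X)[, names(fixed$gamma), drop = FALSE] %*% fixed$gamma)
  } else 0
  ell <- fixed$beta[year] + gpart + omega[knot] +
    epsilon[cbind(knot, year)]
  nll <- sum(observationNLL(b, exp(ell), spec$area, fixed$sigma_m2,
                            spec$family, spec$sigma_param))
  nll <- nll + mvnNLLchol(omega, sqrt(fixed$sigma_omega2) * cholR)
  v1 <- if (spec$init == "stationary") {
    fixed$sigma_eps2 / (1 - fixed$rho_eps^2)
  } else 1
  nll <- nll + mvnNLLchol(epsilon[, 1L], sqrt(v1) * cholR)
  if (n_years > 1L) {
    cholI <- sqrt(fixed$sigma_eps2) * cholR
    for (t in 2:n_years) {
      nll <- nll + mvnNLLchol(epsilon[, t] - fixed$rho_eps * epsilon[, t - 1L],
                              cholI)
    }
  }
  nll
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' Integrates the random fields out of [jointNLL()] by the Laplace
#' approximation: the fields are profiled to their conditional mode by
#' Newton iteration and the curvature correction `0.5 log det H` is added.
#' Exact whenever the observation likelihood is Gaussian in the log
#' predictor (the lognormal family).
#'
#' @inheritParams jointNLL
#' @param inner_tol relative gradient tolerance of the inner optimization.
#' @return the marginal negative log-likelihood of the fixed effects.
#' @export
marginalNLL <- function(fixed, b, knot, year, X = NULL, mesh,
                        spec = sgmSpec(indicator = "none",
                                       include_pc = FALSE),
                        inner_tol = 1e-10) {
  n_years <- max(year)
  Xm <- if (is.null(X)) {
    matrix(0, length(b), 0L)
  } else {
    as.matrix(X)[, spec$covariates, drop = FALSE]
  }
  data <- sgmData(b = b, knot = knot, year_idx = year, X = Xm, a = spec$area,
                  mesh = mesh, n_years = n_years, family = spec$family,
                  sigma_param = spec$sigma_param, init = spec$init,
                  aniso = spec$anisotropy)
  lay <- thetaLayout(n_years, spec$covariates, spec$anisotropy)
  theta <- fixedToTheta(fixed, lay)
  obj <- makeLaplaceObjective(data, lay, inner_tol = inner_tol)
  st <- obj$state(theta)
  if (!st$inner$converged) {
    stop("inner field optimization did not reach tolerance ", inner_tol,
         " (", st$inner$iterations, " iterations)", call. = FALSE)
  }
  st$value
}
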