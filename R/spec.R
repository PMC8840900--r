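#' Model specification for the spatial Gompertz fit
#'
#' Collects the switches that define one model: which covariates enter the
#' log-linked predictor, the observation family, the knot count, the sampled
#' area and the covariance options.
#'
#' @param indicator which biomass covariate carries the indicator effect:
#'   `"tit"` (titmouse group, coefficient gamma1), `"control"` (a random
#'   control group, coefficient gamma4; the quadratic term is always off),
#'   or `"none"` (intercept-and-fields-only model, mainly for testing).
#' @param include_quadratic include the squared (standardized) titmouse
#'   covariate (gamma2)?  Ignored for control-group models.
#' @param include_pc include the environmental productivity score (gamma3)?
#' @param family observation family, `"gamma"` (default) or `"lognormal"`.
#' @param sigma_param gamma dispersion parameterization: `"cv"` (variance
#'   `sigma_m2 * mean^2`, the default) or `"absolute"` (variance `sigma_m2`).
#' @param n_knots number of spatial knots; `NULL` means one knot per unique
#'   sample location.
#' @param area sampled area per point count, km^2.
#' @param anisotropy estimate geometric anisotropy of the Matern field?
#' @param init first-year law of the spatio-temporal field: `"stationary"`
#'   (variance `sigma_eps2 / (1 - rho^2)`, time-homogeneous, default) or
#'   `"unit"` (variance 1).
#' @return an object of class `sgm_spec`.
#' @export
sgmSpec <- function(indicator = c("tit", "control", "none"),
                    include_quadratic = TRUE,
                    include_pc = TRUE,
                    family = c("gamma", "lognormal"),
                    sigma_param = c("cv", "absolute"),
                    n_knots = NULL,
                    area = 0.031,
                    anisotropy = FALSE,
                    init = c("stationary", "unit")) {
  indicator <- match.arg(indicator)
  family <- match.arg(family)
  sigma_param <- match.arg(sigma_param)
  init <- match.arg(init)
  if (!is.null(n_knots) && n_knots < 1L) stop("n_knots must be >= 1")
  if (area <= 0) stop("area must be positive")
  covariates <- c(
    if (indicator != "none") indicator,
    if (indicator == "tit" && include_quadratic) "tit2",
    if (include_pc) "pc"
  )
  structure(list(indicator = indicator,
                 include_quadratic = indicator == "tit" && include_quadratic,
                 include_pc = include_pc,
                 family = family, sigma_param = sigma_param,
                 n_knots = n_knots, area = area,
                 anisotropy = anisotropy, init = init,
                 covariates = covariates),
            class = "sgm_spec")
}

#' @export
print.sgm_spec <- function(x, ...) {
  cat("sgm_spec:", x$family,
      sprintf("(%s dispersion)", x$sigma_param), "\n")
  cat("  predictor: beta(t) + omega(s) + eps(s,t) +",
      paste(x$covariates, collapse = " + "), "\n")
  cat("  knots:", if (is.null(x$n_knots)) "one per location" else x$n_knots,
      " area:", x$area, "km^2",
      " anisotropy:", x$anisotropy, " init:", x$init, "\n")
  invisible(x)
}
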