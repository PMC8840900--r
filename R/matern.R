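#' Geometric anisotropy transform
#'
#' Builds the symmetric positive-definite, unit-determinant 2x2 matrix that
#' maps planar coordinates before distances are computed, from two
#' unconstrained parameters: a rotation angle `psi` (radians) giving the
#' principal decorrelation axis and a log-aspect `h` stretching that axis by
#' `exp(h)` while shrinking the orthogonal one by `exp(-h)`.  `h = 0` is
#' isotropy (the rotation then has no effect).
#'
#' @param psi rotation angle of the principal axis, radians.
#' @param h log-aspect ratio; 0 for isotropy.
#' @return a 2x2 matrix `M` with `det(M) = 1`; transformed coordinates are
#'   `coords %*% t(M)`.
#' @export
anisotropyTransform <- function(psi = 0, h = 0) {
  rot <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2L, 2L)
  rot %*% diag(c(exp(h / 2), exp(-h / 2))) %*% t(rot)
}

#' Matern (nu = 1) spatial correlation matrix
#'
#' Correlation between knot locations under the Matern family with
#' smoothness fixed at one: `rho(d) = (kappa * d) * K1(kappa * d)` where `K1`
#' is the modified Bessel function of the second kind, order 1, and `d` is
#' Euclidean distance after the geometric-anisotropy transform.  `kappa`
#' (1/km) controls the decorrelation distance; correlation drops to ~0.1 near
#' `d = 4 / kappa`.
#'
#' @param coords numeric matrix of knot locations, 2 columns (km, projected).
#' @param log_kappa log of the decorrelation parameter `kappa`.
#' @param aniso numeric length-2 vector `(psi, h)` of anisotropy parameters,
#'   or `NULL` for isotropy.
#' @return symmetric correlation matrix with unit diagonal.
#' @examples
#' xy <- cbind(runif(5, 0, 10), runif(5, 0, 10))
#' R <- maternCorrelation(xy, log_kappa = log(0.5))
#' all(diag(R) == 1)
#' @export
maternCorrelation <- function(coords, log_kappa, aniso = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(aniso) && any(aniso != 0)) {
    coords <- coords %*% t(anisotropyTransform(aniso[1L], aniso[2L]))
  }
  d <- unname(as.matrix(stats::dist(coords)))
  if (any(!is.finite(d))) stop("non-finite distances between knots")
  maternNu1(d, exp(log_kappa))
}

#' Matern nu = 1 correlation as a function of distance
#'
#' @param d non-negative distances.
#' @param kappa decorrelation parameter, > 0.
#' @return correlations, 1 at `d = 0`.
#' @export
maternNu1 <- function(d, kappa) {
  u <- kappa * d
  out <- u # shape
  pos <- u > 0
  out[!pos] <- 1
  out[pos] <- u[pos] * besselK(u[pos], nu = 1)
  # u*K1(u) underflows to NaN*0 for huge u; correlation is numerically 0 there
  out[pos & !is.finite(out)] <- 0
  out
}

# d/d(log kappa) of maternNu1 over a fixed distance matrix:
# u * d/du [u K1(u)] = -u^2 K0(u).
maternNu1DLogKappa <- function(d, kappa) {
  u <- kappa * d
  out <- u
  pos <- u > 0
  out[!pos] <- 0
  out[pos] <- -u[pos]^2 * besselK(u[pos], nu = 0)
  out[pos & !is.finite(out)] <- 0
  out
}
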