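#' Build a spatial knot mesh
#'
#' Random fields are defined at a set of `x` knots; every sample inherits the
#' field value of its nearest knot.  When `x` equals the number of unique
#' sample locations the knots are exactly those locations; when `x` is
#' smaller the knots are the cluster centres of a seeded k-means partition of
#' the unique locations (many survey points then share a knot).
#'
#' @param coords matrix or data.frame of sample locations, columns `x`, `y`
#'   (km, projected planar system).
#' @param x number of knots; must not exceed the number of unique locations.
#' @param seed integer seed for the clustering when `x` is below the number
#'   of unique locations.
#' @return an object of class `knot_mesh`: list with `knots` (x-by-2 matrix)
#'   and `n_knots`.
#' @export
buildKnotMesh <- function(coords, x, seed = 1L) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  uniq <- unique(coords)
  if (x > nrow(uniq)) {
    stop("requested ", x, " knots but only ", nrow(uniq),
         " unique sample locations are available", call. = FALSE)
  }
  if (x == nrow(uniq)) {
    knots <- uniq
  } else if (x == 1L) {
    knots <- matrix(colMeans(uniq), 1L, 2L)
  } else {
    # seeded k-means over unique locations; deterministic given the seed,
    # and the caller's RNG stream is left untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    fit <- stats::kmeans(uniq, centers = x, iter.max = 100L, nstart = 5L)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    knots <- fit$centers
  }
  dimnames(knots) <- list(NULL, c("x", "y"))
  structure(list(knots = knots, n_knots = nrow(knots)), class = "knot_mesh")
}

#' @export
print.knot_mesh <- function(x, ...) {
  cat("knot_mesh with", x$n_knots, "knots\n")
  cat("  x range:", paste(signif(range(x$knots[, 1]), 4), collapse = " .. "),
      "km\n  y range:", paste(signif(range(x$knots[, 2]), 4), collapse = " .. "),
      "km\n")
  invisible(x)
}

#' Map sample locations to their nearest knot
#'
#' Euclidean nearest-knot assignment; ties are broken by the lowest knot
#' index.
#'
#' @param coords matrix of sample locations (2 columns, km).
#' @param mesh a `knot_mesh`.
#' @return integer vector of knot indices, one per row of `coords`.
#' @export
mapToKnots <- function(coords, mesh) {
  stopifnot(inherits(mesh, "knot_mesh"))
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  k <- mesh$knots
  # squared distances sample-by-knot without forming loops
  d2 <- outer(rowSums(coords^2), rep(1, nrow(k))) +
    outer(rep(1, nrow(coords)), rowSums(k^2)) -
    2 * coords %*% t(k)
  max.col(-d2, ties.method = "first")
}
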