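# Environmental covariates: climate screening and annual summaries, the
# PCA-based productivity score, Shannon-entropy habitat classes, and
# covariate standardization.

#' Screen climate grid cells and compute monthly means
#'
#' A site-year is usable only when, in every month, the spread of climate
#' values across the grid cells inside the site's radius is small enough
#' that the site centroid represents the actual sampling points; site-years
#' where any month's cell range strictly exceeds `precip_range_max` or
#' `temp_range_max` are excluded.
#'
#' @param precip_cells,temp_cells lists of length 12 (months), each element
#'   the vector of per-cell values (mm, degrees C) for that month.
#' @param precip_range_max maximum allowed within-month precipitation range
#'   across cells (mm); default 50.
#' @param temp_range_max maximum allowed within-month temperature range
#'   (degrees C); default 11.
#' @return list with `excluded` (logical), `reason` (character or NA),
#'   `precip_monthly`, `temp_monthly` (length-12 means, NULL if excluded).
#' @export
screenClimateCells <- function(precip_cells, temp_cells,
                               precip_range_max = 50, temp_range_max = 11) {
  stopifnot(length(precip_cells) == 12L, length(temp_cells) == 12L)
  if (any(vapply(precip_cells, length, 1L) == 0L) ||
      any(vapply(temp_cells, length, 1L) == 0L)) {
    stop("empty cell list for at least one month", call. = FALSE)
  }
  rng <- function(v) diff(range(v))
  pr <- vapply(precip_cells, rng, numeric(1))
  tr <- vapply(temp_cells, rng, numeric(1))
  if (any(pr > precip_range_max) || any(tr > temp_range_max)) {
    reason <- paste0(
      if (any(pr > precip_range_max)) {
        paste0("precip range ", signif(max(pr), 4), " mm")
      },
      if (any(pr > precip_range_max) && any(tr > temp_range_max)) "; ",
      if (any(tr > temp_range_max)) {
        paste0("temp range ", signif(max(tr), 4), " C")
      })
    return(list(excluded = TRUE, reason = reason,
                precip_monthly = NULL, temp_monthly = NULL))
  }
  list(excluded = FALSE, reason = NA_character_,
       precip_monthly = vapply(precip_cells, mean, numeric(1)),
       temp_monthly = vapply(temp_cells, mean, numeric(1)))
}

#' Annual climate summary
#'
#' @param precip_monthly 12 monthly mean precipitation values (mm).
#' @param temp_monthly 12 monthly mean temperatures (degrees C).
#' @return list with `precip_total` (sum, mm) and `temp_mean` (mean, C).
#' @export
annualClimate <- function(precip_monthly, temp_monthly) {
  if (length(precip_monthly) != 12L || length(temp_monthly) != 12L ||
      anyNA(precip_monthly) || anyNA(temp_monthly)) {
    stop("12 monthly means are required for an annual summary",
         call. = FALSE)
  }
  list(precip_total = sum(precip_monthly), temp_mean = mean(temp_monthly))
}

#' Environmental productivity score from annual climate
#'
#' Principal component analysis (correlation matrix: both variables are
#' standardized) of annual precipitation totals and mean temperatures over
#' site-years.  Productivity rises with both precipitation and temperature,
#' so the component whose loadings on both variables are positive is the
#' productivity proxy; a component with two negative loadings is
#' sign-flipped.  With two variables one of the two components always
#' qualifies except at exactly zero correlation, where component 1 is taken.
#'
#' @param climate data.frame with columns `site_id`, `year`,
#'   `precip_total`, `temp_mean`; at least 3 rows.
#' @return data.frame `site_id`, `year`, `pc` (the score), with attributes
#'   `component` (1 or 2), `loadings` (named length-2 vector) and
#'   `sdev` (the component's standard deviation).
#' @export
productivityIndex <- function(climate) {
  stopifnot(all(c("site_id", "year", "precip_total", "temp_mean") %in%
                  names(climate)))
  if (nrow(climate) < 3L) stop("need at least 3 site-years", call. = FALSE)
  M <- cbind(precip = climate$precip_total, temp = climate$temp_mean)
  if (any(apply(M, 2L, stats::sd) == 0)) {
    stop("zero variance in precipitation or temperature", call. = FALSE)
  }
  pca <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  pick <- NA_integer_
  for (k in 1:2) {
    ld <- pca$rotation[, k]
    if (all(ld > 0)) { pick <- k; break }
    if (all(ld < 0)) {
      pca$rotation[, k] <- -ld
      pca$x[, k] <- -pca$x[, k]
      pick <- k
      break
    }
  }
  if (is.na(pick)) pick <- 1L  # zero-correlation tie: component 1
  if (pca$sdev[pick] < 1e-8) {
    warning("selected component has (near-)zero variance", call. = FALSE)
  }
  out <- data.frame(site_id = climate$site_id, year = climate$year,
                    pc = pca$x[, pick])
  attr(out, "component") <- pick
  attr(out, "loadings") <- pca$rotation[, pick]
  attr(out, "sdev") <- pca$sdev[pick]
  out
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum p_k log p_k` in nats over categories with positive abundance.
#'
#' @param abundances non-negative vector with a positive sum.
#' @return the index (nats).
#' @examples
#' shannonIndex(rep(5, 4))  # log(4)
#' @export
shannonIndex <- function(abundances) {
  if (any(abundances < 0) || sum(abundances) <= 0) {
    stop("abundances must be non-negative with a positive sum",
         call. = FALSE)
  }
  p <- abundances[abundances > 0] / sum(abundances)
  -sum(p * log(p))
}

#' Merge habitats into main classes by Shannon entropy
#'
#' Within each structurally defined group of habitat codes, habitats whose
#' diversity indices lie within `tolerance` of each other are merged into
#' one class: habitats are taken in order of increasing `H'` and a new
#' class starts whenever the gap to the current class's first member
#' exceeds the tolerance.  Labels are deterministic:
#' `<group>_c<running index>`.
#'
#' @param h_prime named numeric vector: Shannon index per habitat code.
#' @param structural_groups named character vector or list mapping each
#'   habitat code to its structural group.
#' @param tolerance maximum within-class spread of `H'` (nats), default 0.1.
#' @return data.frame `habitat_code`, `h_prime`, `group`, `class_label`.
#' @export
assignHabitatClasses <- function(h_prime, structural_groups,
                                 tolerance = 0.1) {
  codes <- names(h_prime)
  grp <- unlist(structural_groups)[codes]
  if (anyNA(grp)) {
    stop("habitat code(s) missing from structural_groups: ",
         paste(codes[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(habitat_code = codes, h_prime = unname(h_prime),
                    group = unname(grp), class_label = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in unique(out$group)) {
    i <- which(out$group == g)
    i <- i[order(out$h_prime[i])]
    cls <- 0L
    anchor <- -Inf
    for (j in i) {
      if (out$h_prime[j] - anchor > tolerance) {
        cls <- cls + 1L
        anchor <- out$h_prime[j]
      }
      out$class_label[j] <- paste0(g, "_c", cls)
    }
  }
  out[order(out$habitat_code), ]
}

#' Standardize a covariate
#'
#' Centers to mean zero and scales to unit standard deviation (denominator
#' n - 1).
#'
#' @param values numeric vector, length >= 2, positive variance.
#' @return the standardized vector.
#' @export
standardizeCovariate <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("zero variance; cannot standardize", call. = FALSE)
  }
  (values - mean(values)) / s
}
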