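# Shared toy builders for the likelihood and fitting tests.

# A small fully specified model problem with known dimensions.
toy_problem <- function(x = 6, n_years = 3, n_per = 2, seed = 42,
                        family = "gamma") {
  set.seed(seed)
  mesh <- buildKnotMesh(cbind(runif(x, 0, 10), runif(x, 0, 10)), x)
  n <- x * n_years * n_per
  knot <- rep(seq_len(x), n_years * n_per)
  year <- rep(rep(seq_len(n_years), each = x), n_per)
  X <- cbind(tit = rnorm(n), pc = rnorm(n))
  spec <- sgmSpec(indicator = "tit", include_quadratic = FALSE,
                  include_pc = TRUE, area = 1, family = family)
  fixed <- list(beta = seq(2.0, by = 0.1, length.out = n_years),
                gamma = c(tit = 0.2, pc = -0.1), sigma_m2 = 0.5,
                kappa = 0.3, aniso = c(0, 0), rho_eps = 0.4,
                sigma_omega2 = 0.4, sigma_eps2 = 0.2)
  b <- rgamma(n, shape = 2, scale = 5)
  list(mesh = mesh, knot = knot, year = year, X = X, b = b,
       spec = spec, fixed = fixed, x = x, n_years = n_years, n = n)
}

# Toy ingestion inputs: 2 sites x 2 points, 2 years, small community.
toy_survey <- function() {
  counts <- data.frame(
    site_id = rep(c("A", "A", "B", "B"), each = 4),
    point_id = rep(c("A1", "A2", "B1", "B2"), each = 4),
    year = rep(c(2001L, 2001L, 2002L, 2002L), 4),
    period = 1L,
    species_code = rep(c("TIT1", "WARB", "TIT1", "CROW"), 4),
    count = c(2L, 3L, 1L, 2L,  1L, 2L, 2L, 1L,
              3L, 1L, 1L, 1L,  2L, 2L, 2L, 2L),
    habitat_code = "forest",
    stringsAsFactors = FALSE)
  traits <- data.frame(
    species_code = c("TIT1", "WARB", "CROW", "WADR"),
    body_mass = c(10, 20, 500, 150),
    is_titmouse = c(TRUE, FALSE, FALSE, FALSE),
    is_excluded_guild = c(FALSE, FALSE, FALSE, TRUE),
    is_forest = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  locations <- data.frame(
    site_id = c("A", "A", "B", "B"),
    point_id = c("A1", "A2", "B1", "B2"),
    x = c(0, 1, 10, 11), y = c(0, 1, 10, 11),
    stringsAsFactors = FALSE)
  list(counts = counts, traits = traits, locations = locations)
}

write_counts_file <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

as_point_counts <- function(df, mode = "individual_counts") {
  structure(df, mode = mode, class = c("point_counts", "data.frame"))
}
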