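mk_months <- function(base, spread = 0) {
  lapply(1:12, function(m) base[m] + c(-spread / 2, spread / 2))
}

test_that("climate screening excludes on strict range exceedance only", {
  p_ok <- mk_months(rep(30, 12), spread = 50)   # exactly at the threshold
  t_ok <- mk_months(rep(10, 12), spread = 11)
  scr <- screenClimateCells(p_ok, t_ok)
  expect_false(scr$excluded)
  expect_equal(scr$precip_monthly, rep(30, 12))
  # one month with cells {10, 65}: range 55 > 50 mm
  p_bad <- mk_months(rep(30, 12)); p_bad[[4]] <- c(10, 65)
  expect_true(screenClimateCells(p_bad, t_ok)$excluded)
  t_bad <- mk_months(rep(10, 12), spread = 11.5)
  expect_true(screenClimateCells(p_ok, t_bad)$excluded)
  # single-cell sites always pass, means are the cell values
  p1 <- lapply(1:12, function(m) 100 + m)
  t1 <- lapply(1:12, function(m) m)
  scr1 <- screenClimateCells(p1, t1)
  expect_false(scr1$excluded)
  expect_equal(scr1$temp_monthly, 1:12)
  expect_error(screenClimateCells(c(p1[-1], list(numeric(0))), t1), "empty")
})

test_that("exclusions shrink as thresholds relax", {
  set.seed(31)
  n_excl <- function(pmax, tmax) {
    sum(vapply(1:40, function(i) {
      set.seed(1000 + i)
      p <- lapply(1:12, function(m) runif(4, 0, 60))
      tc <- lapply(1:12, function(m) runif(4, 0, 14))
      screenClimateCells(p, tc, pmax, tmax)$excluded
    }, logical(1)))
  }
  e1 <- n_excl(30, 7); e2 <- n_excl(50, 11); e3 <- n_excl(70, 15)
  expect_true(e1 >= e2 && e2 >= e3)
})

test_that("annual climate sums precipitation and averages temperature", {
  ac <- annualClimate(rep(10, 12), c(rep(0, 6), rep(10, 6)))
  expect_equal(ac$precip_total, 120)
  expect_equal(ac$temp_mean, 5)
  expect_error(annualClimate(rep(10, 11), rep(1, 12)), "12 monthly")
  expect_error(annualClimate(c(rep(10, 11), NA), rep(1, 12)), "12 monthly")
})

test_that("productivity index picks the positively loaded component", {
  # perfectly correlated pair: loadings (1, 1)/sqrt(2); the score of a row
  # one SD above the mean in both variables is sqrt(2)
  cl <- data.frame(site_id = letters[1:5], year = 2001,
                   precip_total = c(100, 200, 300, 400, 500),
                   temp_mean = c(1, 2, 3, 4, 5))
  pr <- productivityIndex(cl)
  expect_equal(unname(attr(pr, "loadings")), rep(1 / sqrt(2), 2))
  z <- (cl$precip_total - 300) / sd(cl$precip_total)
  expect_equal(pr$pc, sqrt(2) * z, tolerance = 1e-10)
  # anticorrelated pair: the qualifying component has zero variance
  cl2 <- cl; cl2$temp_mean <- rev(cl2$temp_mean)
  expect_warning(pr2 <- productivityIndex(cl2), "zero variance")
  expect_true(all(attr(pr2, "loadings") > 0))
  expect_error(productivityIndex(cl[c(1, 1, 1), ]), "variance")
})

test_that("productivity scores are invariant to affine input rescaling", {
  set.seed(32)
  cl <- data.frame(site_id = 1:30, year = 2001,
                   precip_total = runif(30, 300, 900),
                   temp_mean = runif(30, 2, 12))
  cl$temp_mean <- cl$temp_mean + 0.004 * cl$precip_total  # induce correlation
  p1 <- productivityIndex(cl)
  cl2 <- cl
  cl2$precip_total <- 3 * cl2$precip_total + 100
  cl2$temp_mean <- 0.5 * cl2$temp_mean - 4
  expect_equal(productivityIndex(cl2)$pc, p1$pc, tolerance = 1e-10)
})

test_that("Shannon index matches direct summation and its extremes", {
  expect_equal(shannonIndex(rep(5, 4)), log(4))
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p), -sum(p * log(p)))
  expect_equal(shannonIndex(p), 1.0397, tolerance = 1e-4)
  expect_equal(shannonIndex(c(2, 0, 1, 1)), shannonIndex(c(1, 2, 1, 0)))
  expect_error(shannonIndex(c(0, 0)), "positive sum")
  # uniform maximizes entropy among random compositions
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    expect_lte(shannonIndex(rgamma(k, 1)), log(k) + 1e-12)
  }
})

test_that("habitat classes merge within tolerance inside structural groups", {
  groups <- c(h1 = "open", h2 = "open", h3 = "closed", h4 = "closed")
  out <- assignHabitatClasses(c(h1 = 1.10, h2 = 1.12, h3 = 0.2, h4 = 1.5),
                              groups, tolerance = 0.05)
  expect_equal(out$class_label[out$habitat_code %in% c("h1", "h2")],
               rep("open_c1", 2))
  expect_length(unique(out$class_label[out$habitat_code %in%
                                         c("h3", "h4")]), 2L)
  # tolerance 0: classes are the distinct index values
  out0 <- assignHabitatClasses(c(h1 = 1.1, h2 = 1.1, h3 = 1.2),
                               c(h1 = "g", h2 = "g", h3 = "g"),
                               tolerance = 0)
  expect_equal(out0$class_label, c("g_c1", "g_c1", "g_c2"))
  expect_error(assignHabitatClasses(c(h1 = 1, hX = 2), c(h1 = "g")),
               "hX")
})

test_that("standardization centers, scales, and is idempotent", {
  expect_equal(standardizeCovariate(c(1, 2, 3)), c(-1, 0, 1))
  v <- rnorm(50, 3, 2)
  z <- standardizeCovariate(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardizeCovariate(z), z, tolerance = 1e-12)
  expect_error(standardizeCovariate(rep(2, 5)), "zero variance")
  expect_error(standardizeCovariate(3), "at least 2")
})
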