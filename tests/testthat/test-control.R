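test_that("control-group draws are reproducible six-species sets", {
  pool <- sprintf("SP%02d", 1:20)
  g1 <- drawControlGroups(pool, n_groups = 10, seed = 5)
  g2 <- drawControlGroups(pool, n_groups = 10, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(vapply(g1, function(g) length(unique(g)) == 6L,
                         logical(1))))
  expect_true(all(unlist(g1) %in% pool))
  # a pool of exactly six forces every draw
  g3 <- drawControlGroups(pool[1:6], n_groups = 4, seed = 1)
  expect_true(all(vapply(g3, identical, logical(1), sort(pool[1:6]))))
  expect_error(drawControlGroups(pool[1:5], seed = 1), "smaller")
  expect_error(drawControlGroups(pool), "seed")
})

test_that("control response moves group biomass out of b and drops empty samples", {
  toy <- toy_survey()
  rec <- applyGuildFilters(as_point_counts(toy$counts), toy$traits)
  # group = {WARB, CROW} strips every non-titmouse species: all b become 0
  s_all <- controlResponse(rec, toy$traits, toy$locations,
                           c("WARB", "CROW"))
  expect_equal(nrow(s_all), 0L)
  expect_equal(attr(s_all, "n_zero_removed"), 8L)
  # a 3-species toy keeps hand-computed books
  rec1 <- as_point_counts(data.frame(
    site_id = "A", point_id = "A1", year = c(2001, 2001, 2001),
    period = 1, species_code = c("TIT1", "WARB", "CROW"),
    count = c(2L, 3L, 1L), habitat_code = "f"))
  s <- controlResponse(rec1, toy$traits, toy$locations, "CROW")
  expect_equal(s$b, 60)        # 3 x 20 g warbler
  expect_equal(s$control, 500) # 1 x 500 g crow
  expect_equal(s$tit, 20)      # 2 x 10 g titmouse
  # the empty group reproduces the main-analysis response
  s0 <- controlResponse(rec, toy$traits, toy$locations, character(0))
  main <- buildSamples(rec, toy$traits, toy$locations)
  expect_equal(s0$b, main$b[main$b > 0])
})

cf <- function(g4, lo, hi, converged = TRUE) {
  list(group_id = "g", gamma4 = g4, se = 1, ci = c(lo, hi),
       converged = converged,
       significant = isTRUE(lo > 0 || hi < 0))
}

test_that("classification applies the zero test before the titmouse comparison", {
  g1 <- 0.025
  expect_equal(classifyControl(cf(0.05, 0.030, 0.062), g1), "stronger")
  expect_equal(classifyControl(cf(0.01, 0.001, 0.020), g1), "weaker")
  # encompasses zero (and gamma1): zero test wins
  expect_equal(classifyControl(cf(0.02, -0.01, 0.05), g1), "not_significant")
  expect_equal(classifyControl(cf(0.03, 0.01, 0.05), g1), "not_different")
  # closed intervals: endpoint equality encompasses
  expect_equal(classifyControl(cf(0.03, 0, 0.05), g1), "not_significant")
  expect_equal(classifyControl(cf(0.03, 0.025, 0.05), g1), "not_different")
  expect_error(classifyControl(cf(0.03, 0.01, 0.05, converged = FALSE), g1),
               "non-converged")
})

test_that("summaries count classes and report proportions among significant fits", {
  g1 <- 0.025
  xs <- c(replicate(3, cf(0.05, 0.03, 0.062), simplify = FALSE),
          replicate(2, cf(0.01, 0.001, 0.02), simplify = FALSE),
          replicate(4, cf(0.03, 0.01, 0.05), simplify = FALSE),
          replicate(5, cf(0.02, -0.01, 0.05), simplify = FALSE),
          list(cf(NA, NA, NA, converged = FALSE)))
  rep <- summarizeControls(xs, g1)
  expect_equal(rep$n_drawn, 15L)
  expect_equal(rep$n_converged, 14L)
  expect_equal(rep$n_significant, 9L)
  expect_equal(rep$n_stronger, 3L)
  expect_equal(rep$n_weaker, 2L)
  expect_equal(rep$pct_stronger, round(100 * 3 / 9, 1))
  expect_equal(rep$gamma4_mean, mean(c(rep(0.05, 3), rep(0.01, 2),
                                       rep(0.03, 4))))
  expect_equal(rep$gamma4_min, 0.01)
  # order invariance of all counts
  rep2 <- summarizeControls(rev(xs), g1)
  expect_equal(rep2[setdiff(names(rep2), "classes")],
               rep[setdiff(names(rep), "classes")], ignore_attr = TRUE)
  # degenerate inputs: no significant fits, proportions undefined not zero
  rep3 <- summarizeControls(list(cf(0.02, -0.01, 0.05)), g1)
  expect_true(is.na(rep3$pct_stronger))
  expect_output(print(rep3), "no significant")
  # single significant group: proportions land on 0 or 100
  rep4 <- summarizeControls(list(cf(0.05, 0.03, 0.062)), g1)
  expect_equal(rep4$pct_stronger, 100)
  expect_equal(rep4$pct_weaker, 0)
})

test_that("a known control effect is recovered and flags propagate", {
  cfg <- simConfig(n_sites = 40, n_years = 5,
                   gamma = c(control = 0.15), seed = 61)
  sim <- simulateObservations(cfg)
  spec <- sgmSpec(indicator = "control", include_pc = FALSE)
  got <- fitControl(sim$samples, spec = spec, mesh = sim$mesh,
                    group_id = "toy", seed = 61)
  expect_true(got$converged)
  expect_true(got$ci[1] <= 0.15 && 0.15 <= got$ci[2])
  expect_equal(got$gamma4, 0.15, tolerance = 0.1)
  expect_error(fitControl(sim$samples, spec = sgmSpec(indicator = "tit")),
               "linear control")
  # an unfittable input propagates as a non-converged summary
  bad <- sim$samples[sim$samples$year == 2001, ]
  nc <- fitControl(bad, spec = spec, group_id = "bad")
  expect_false(nc$converged)
  expect_true(is.na(nc$gamma4))
})
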