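test_that("point-count files read back row for row", {
  toy <- toy_survey()
  path <- write_counts_file(toy$counts[1:3, ])
  rec <- readPointCounts(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$count, toy$counts$count[1:3])
  expect_identical(attr(rec, "mode"), "individual_counts")
})

test_that("duplicate key rows are summed with a warning", {
  df <- data.frame(site_id = "A", point_id = "P", year = 2001, period = 1,
                   species_code = "SP", count = c(1L, 2L),
                   habitat_code = "f")
  path <- write_counts_file(df)
  expect_warning(rec <- readPointCounts(path), "duplicate")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$count, 3L)
})

test_that("column mapping failures and bad counts are configuration errors", {
  df <- data.frame(site_id = "A", point_id = "P", year = 2001,
                   count = 1L)  # species column missing
  expect_error(readPointCounts(write_counts_file(df)), "species_code")
  df2 <- data.frame(site = "A", point = "P", yr = 2001, sp = "X", n = 2L)
  rec <- readPointCounts(write_counts_file(df2),
                         dialect = list(site_id = "site", point_id = "point",
                                        year = "yr", species_code = "sp",
                                        count = "n"))
  expect_equal(rec$count, 2L)
  df3 <- data.frame(site_id = "A", point_id = "P", year = 2001,
                    species_code = "X", count = 1.5)
  expect_error(readPointCounts(write_counts_file(df3)), "row")
})

test_that("pair doubling doubles once and only once", {
  toy <- toy_survey()
  rec <- as_point_counts(toy$counts, "pair_counts")
  ind <- pairsToIndividuals(rec)
  expect_equal(ind$count, toy$counts$count * 2L)
  expect_equal(pairsToIndividuals(as_point_counts(
    data.frame(toy$counts[1, ], row.names = NULL)[rep(1, 1), ],
    "pair_counts"))$count, toy$counts$count[1] * 2L)
  expect_error(pairsToIndividuals(ind), "refusing to double")
  zero <- toy$counts[1, ]; zero$count <- 0L
  expect_equal(pairsToIndividuals(as_point_counts(zero, "pair_counts"))$count,
               0L)
})

test_that("breeding periods sum within site/point/year/species", {
  df <- data.frame(site_id = "A", point_id = "P", year = 2001,
                   period = c(1L, 2L, 2L),
                   species_code = c("X", "X", "Y"),
                   count = c(2L, 5L, 4L), habitat_code = "f")
  m <- mergeBreedingPeriods(as_point_counts(df))
  expect_equal(m$count[m$species_code == "X"], 7L)
  # a species seen only in period 2 is retained
  expect_equal(m$count[m$species_code == "Y"], 4L)
  expect_true(all(m$period == 1L))
  # single-period input is unchanged
  single <- as_point_counts(toy_survey()$counts)
  expect_equal(mergeBreedingPeriods(single)$count, single$count)
})

test_that("guild filters drop excluded guilds and non-forest species", {
  toy <- toy_survey()
  rec <- as_point_counts(rbind(
    toy$counts[1:2, ],
    data.frame(site_id = "A", point_id = "A1", year = 2001, period = 1,
               species_code = "WADR", count = 1L, habitat_code = "f")))
  out <- applyGuildFilters(rec, toy$traits)
  expect_equal(nrow(out), 2L)
  expect_false("WADR" %in% out$species_code)
  # all-forest, nothing excluded: identity
  expect_equal(nrow(applyGuildFilters(as_point_counts(toy$counts),
                                      toy$traits)), nrow(toy$counts))
  bad <- as_point_counts(data.frame(site_id = "A", point_id = "A1",
                                    year = 2001, period = 1,
                                    species_code = "NOPE", count = 1L,
                                    habitat_code = "f"))
  expect_error(applyGuildFilters(bad, toy$traits), "NOPE")
})

test_that("sample biomass follows hand-computed sums", {
  toy <- toy_survey()
  # 2 individuals of a 10 g titmouse and 3 of a 20 g warbler
  rec <- as_point_counts(data.frame(
    site_id = "A", point_id = "A1", year = 2001, period = 1,
    species_code = c("TIT1", "WARB"), count = c(2L, 3L),
    habitat_code = "f"))
  s <- buildSamples(rec, toy$traits, toy$locations, area = 0.031)
  expect_equal(s$tit, 20)
  expect_equal(s$b, 60)
  expect_equal(s$area, 0.031)
  expect_equal(s[, c("x", "y")], data.frame(x = 0, y = 0))
  # moving the warbler into a control group moves its biomass
  s2 <- buildSamples(rec, toy$traits, toy$locations, area = 0.031,
                     control_species = "WARB")
  expect_equal(s2$b, 0)
  expect_equal(s2$control, 60)
  expect_equal(s2$tit, 20)
  expect_error(buildSamples(rec, toy$traits, toy$locations,
                            control_species = "TIT1"), "titmouse")
})

test_that("biomass is conserved through sample building", {
  toy <- toy_survey()
  rec <- applyGuildFilters(as_point_counts(toy$counts), toy$traits)
  mass <- toy$traits$body_mass[match(rec$species_code,
                                     toy$traits$species_code)]
  total <- sum(rec$count * mass)
  for (ctrl in list(NULL, "WARB", c("WARB", "CROW"))) {
    s <- buildSamples(rec, toy$traits, toy$locations,
                      control_species = ctrl)
    expect_identical(sum(s$b + s$tit + s$control), total)
  }
})

test_that("pair doubling before aggregation doubles every biomass", {
  toy <- toy_survey()
  rec_pairs <- as_point_counts(toy$counts, "pair_counts")
  rec_ind <- pairsToIndividuals(rec_pairs)
  s1 <- buildSamples(applyGuildFilters(rec_ind, toy$traits), toy$traits,
                     toy$locations)
  s0 <- buildSamples(applyGuildFilters(as_point_counts(toy$counts),
                                       toy$traits), toy$traits,
                     toy$locations)
  expect_equal(s1$b, 2 * s0$b)
  expect_equal(s1$tit, 2 * s0$tit)
})

test_that("period merging commutes with guild filtering", {
  toy <- toy_survey()
  df <- toy$counts
  df$period <- rep(c(1L, 2L), length.out = nrow(df))
  df <- rbind(df, data.frame(site_id = "A", point_id = "A1", year = 2001,
                             period = 2L, species_code = "WADR", count = 3L,
                             habitat_code = "f"))
  rec <- as_point_counts(df)
  a <- applyGuildFilters(mergeBreedingPeriods(rec), toy$traits)
  b <- mergeBreedingPeriods(applyGuildFilters(rec, toy$traits))
  key <- function(d) d[order(d$site_id, d$point_id, d$year, d$species_code),
                       c("site_id", "point_id", "year", "species_code",
                         "count")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("points without coordinates fall back to the site centroid", {
  toy <- toy_survey()
  rec <- as_point_counts(toy$counts[1:2, ])
  loc <- data.frame(site_id = c("A", "A"), point_id = c("A2", "A3"),
                    x = c(2, 4), y = c(0, 2))
  s <- buildSamples(rec, toy$traits, loc)
  expect_equal(unique(s$x), 3)
  expect_equal(unique(s$y), 1)
  expect_error(buildSamples(rec, toy$traits,
                            loc[loc$site_id == "none", ]), "location")
})
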