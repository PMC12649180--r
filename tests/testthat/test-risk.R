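test_that("component indices follow their normalizations", {
  expect_equal(abundance_index(c(A = 20, B = 5)), c(A = 100, B = 25))
  expect_equal(abundance_index(c(A = 3)), c(A = 100))
  expect_error(abundance_index(c(A = 0)), "all-zero")

  # flock: one species seen once with 10 birds, another 10 times with 1
  sv <- make_survey(
    species_id = c("big", rep("solo", 10)),
    transect_id = "t1", habitat = "forest", season = "spring",
    count = c(10L, rep(1L, 10)), height_band = "B0_5", zone = "outside")
  fl <- flock_index(sv)
  expect_equal(fl$flock_size[fl$species_id == "big"], 10)
  expect_equal(fl$flock_size[fl$species_id == "solo"], 1)
  expect_equal(fl$G[fl$species_id == "big"], 100)
  expect_equal(fl$G[fl$species_id == "solo"], 10)
  # all solitary -> all G = 100
  sv2 <- make_survey(species_id = c("a", "b"), transect_id = "t1",
                     habitat = "forest", season = "spring",
                     count = c(1L, 1L), height_band = "B0_5",
                     zone = "outside")
  expect_equal(flock_index(sv2)$G, c(100, 100))

  # spatial: forest 300 + wetland 100
  areas <- as_habitat_areas(c(forest = 300, wetland = 100))
  sv3 <- make_survey(
    species_id = c("w", "f", "both", "both"),
    transect_id = c("t2", "t1", "t1", "t2"),
    habitat = c("wetland", "forest", "forest", "wetland"),
    season = "spring", count = 1L, height_band = "B0_5", zone = "outside")
  s <- spatial_index(sv3, areas)
  expect_equal(s[["w"]], 25)
  expect_equal(s[["f"]], 75)
  expect_equal(s[["both"]], 100)
  expect_error(spatial_index(make_survey(
    species_id = "x", transect_id = "t9", habitat = "urban",
    season = "spring", count = 1L, height_band = "B0_5",
    zone = "outside"), areas), "habitat missing")

  # mass: 1000 g vs 250 g
  tr <- make_traits(c("h", "l"), mass = c(1000, 250), hwi = c(10, 10),
                    diet = "x", stratum = "g")
  expect_equal(mass_index(tr), c(h = 100, l = 25))
})

test_that("height coefficient uses the modal band, ties toward higher risk", {
  bands <- c("B30_50", "B0_5", "B100plus")
  expect_equal(unname(HEIGHT_COEF[bands]), c(1.0, 0.1, 0.1))
  sv <- make_survey(
    species_id = rep("s", 4), transect_id = "t1", habitat = "forest",
    season = "spring", count = 1L,
    height_band = c("B5_30", "B5_30", "B30_50", "B30_50"),
    zone = "outside")
  expect_equal(height_coefficient(sv)[["s"]], 1.0)  # tie -> larger coef
  sv2 <- make_survey(
    species_id = rep("s", 3), transect_id = "t1", habitat = "forest",
    season = "spring", count = 1L,
    height_band = c("B0_5", "B0_5", "B30_50"), zone = "outside")
  expect_equal(height_coefficient(sv2)[["s"]], 0.1)  # clear mode
  # all bands missing: error, or drop under the flag
  sv3 <- rbind(survey_row("a", band = NA), survey_row("b", band = "B0_5"))
  sv3 <- as_survey_table(sv3)
  expect_error(height_coefficient(sv3), "no height-band")
  expect_message(h <- height_coefficient(sv3, allow_drop = TRUE),
                 "dropping")
  expect_equal(names(h), "b")
})

test_that("zone coefficient is 0.5 with any inside record, else 0.1", {
  sv <- make_survey(
    species_id = c("in", "out", "mix", "mix"),
    transect_id = "t1", habitat = "urban", season = "spring", count = 1L,
    height_band = "B0_5",
    zone = c("inside", "outside", "outside", "inside"))
  d <- zone_coefficient(sv)
  expect_equal(d[["in"]], 0.5)
  expect_equal(d[["out"]], 0.1)
  expect_equal(d[["mix"]], 0.5)
})

test_that("risk value combines exactly and classifies the boundaries", {
  expect_equal(as.character(risk_tier(c(75, 25, 24.99, 15, 14.99, 5, 4.99))),
               c("extremely_high", "extremely_high", "high", "high",
                 "moderate", "moderate", "low"))
  # maximal case: N=G=S=W=100, H=1, D=0.5 -> IV=100, F=0.75, R=75
  sv <- make_survey(
    species_id = "top", transect_id = "t1", habitat = "forest",
    season = "spring", count = 1L, height_band = "B30_50", zone = "inside")
  areas <- as_habitat_areas(c(forest = 100))
  tr <- make_traits("top", mass = 500, hwi = 20, diet = "x", stratum = "g")
  r <- assess_risk(sv, tr, areas)
  expect_equal(r$IV, 100)
  expect_equal(r$F, 0.75)
  expect_equal(r$R, 75)
  expect_equal(as.character(r$tier), "extremely_high")
})

test_that("assessment obeys identities, bounds, and scale invariance", {
  cfg <- sim_config(n_species = 30,
                    n_transects = c(urban = 1, farmland = 1, forest = 1,
                                    wetland = 1), seed = 99)
  ds <- simulate_dataset(cfg)
  r <- assess_risk(ds$survey, ds$traits, ds$areas)
  expect_equal(r$IV, (r$N + r$G + r$S + r$W) / 4, tolerance = 1e-12)
  expect_equal(r$F, (r$H + r$D) / 2, tolerance = 1e-12)
  expect_equal(r$R, r$IV * r$F, tolerance = 1e-12)
  expect_true(all(r$R >= 0 & r$R <= 75))
  expect_true(all(r$N > 0 & r$N <= 100) && any(r$N == 100))
  expect_true(any(r$G == 100) && any(r$W == 100))
  expect_true(all(r$H %in% c(0.1, 0.5, 1.0)))
  expect_true(all(r$D %in% c(0.1, 0.5)))
  # multiplying all counts by a constant leaves N and tiers unchanged
  sv2 <- ds$survey
  sv2$count <- sv2$count * 5L
  r2 <- assess_risk(as_survey_table(as.data.frame(sv2)), ds$traits, ds$areas)
  expect_equal(r2$N, r$N, tolerance = 1e-12)
  expect_equal(r2[order(r2$species_id), "tier"],
               r[order(r$species_id), "tier"])
})

test_that("risk report computes tier shares with half-up rounding", {
  rep1 <- risk_report(c(extremely_high = 2, high = 3, moderate = 30,
                        low = 113))
  expect_equal(rep1$count, c(2, 3, 30, 113))
  expect_equal(rep1$share, c(1.35, 2.03, 20.27, 76.35))
  expect_equal(sum(rep1$count), 148)
  expect_lt(abs(sum(rep1$share) - 100), 0.05)
  rep2 <- risk_report(c(low = 7))
  expect_equal(rep2$share, c(0, 0, 0, 100))
  expect_error(risk_report(c(medium = 1)), "unknown tier")
})
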