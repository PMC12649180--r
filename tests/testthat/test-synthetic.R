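test_that("config validates its parameters", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(n_species = 1, seed = 1), "n_species")
  expect_error(sim_config(birth_rate = 0, seed = 1), "birth_rate")
  expect_error(sim_config(detection_rate = 0, seed = 1), "detection_rate")
  expect_error(sim_config(n_transects = c(meadow = 2), seed = 1),
               "unknown habitat")
})

test_that("yule trees have the right shape and expected depth", {
  tr <- simulate_tree(sim_config(n_species = 2, seed = 1))
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(tr$Nnode, 1L)
  # determinism
  a <- simulate_tree(sim_config(n_species = 12, seed = 9))
  b <- simulate_tree(sim_config(n_species = 12, seed = 9))
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(ape::is.ultrametric(a, tol = 1e-8))
  expect_true(all(a$edge.length >= 0))
  # expected root-to-tip depth: sum of Exp(b k) waits for k = 2..n
  n <- 50; b_rate <- 2
  exp_depth <- sum(1 / (b_rate * (2:n)))
  depths <- vapply(1:200, function(s) {
    t <- simulate_tree(sim_config(n_species = n, birth_rate = b_rate,
                                  seed = 1000 + s))
    max(ape::node.depth.edgelength(t))
  }, numeric(1))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - exp_depth), 4 * se)
})

test_that("trait evolution respects signal strength and determinism", {
  cfg0 <- sim_config(n_species = 10, trait_signal = 0, seed = 5)
  tr <- simulate_tree(cfg0)
  t0 <- simulate_traits(tr, cfg0)
  expect_equal(t0$body_mass, rep(80, 10))   # degenerate BM: root state
  expect_equal(t0$hwi, rep(25, 10))
  cfg1 <- sim_config(n_species = 10, seed = 5)
  t1a <- simulate_traits(tr, cfg1)
  t1b <- simulate_traits(tr, cfg1)
  expect_identical(t1a, t1b)
  # BM variance grows with independent path length: sister tips joined by
  # tiny branches differ less than distant tips, on average over replicates
  close_diff <- numeric(50); far_diff <- numeric(50)
  for (s in 1:50) {
    cfg <- sim_config(n_species = 6, seed = 2000 + s)
    tre <- simulate_tree(cfg)
    pd <- stats::cophenetic(tre)
    pairs <- t(combn(rownames(pd), 2))
    dd <- apply(pairs, 1, function(p) pd[p[1], p[2]])
    tt <- simulate_traits(tre, cfg)
    lm <- setNames(log(tt$body_mass), tt$species_id)
    md <- apply(pairs, 1, function(p) abs(lm[p[1]] - lm[p[2]]))
    close_diff[s] <- mean(md[dd <= median(dd)])
    far_diff[s] <- mean(md[dd > median(dd)])   # NaN when distances tie
  }
  expect_lt(mean(close_diff, na.rm = TRUE), mean(far_diff, na.rm = TRUE))
})

test_that("risk attributes bias heavy species upward and honor fractions", {
  cfg <- sim_config(n_species = 60, seed = 31)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  ra <- simulate_risk_attributes(tt, cfg)
  band_rank <- match(ra$pref_band, HEIGHT_BANDS)
  heavy <- tt$body_mass > median(tt$body_mass)
  expect_gt(mean(band_rank[heavy]), mean(band_rank[!heavy]))
  expect_equal(sum(ra$inside_user), round(0.2 * 60))
  # fraction 0 -> all species outside-only -> D = 0.1 everywhere
  cfg0 <- sim_config(n_species = 20, inside_fraction = 0,
                     n_transects = c(forest = 2), seed = 8)
  ds0 <- simulate_dataset(cfg0)
  expect_true(all(zone_coefficient(ds0$survey) == 0.1))
  # fraction 1 -> every observed species has an inside record -> D = 0.5
  cfg1 <- sim_config(n_species = 20, inside_fraction = 1,
                     n_transects = c(forest = 2), seed = 8)
  ds1 <- simulate_dataset(cfg1)
  expect_true(all(zone_coefficient(ds1$survey) == 0.5))
})

test_that("survey generation is deterministic and conserves abundance", {
  cfg <- sim_config(n_species = 20, n_transects = c(wetland = 2), seed = 77)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(ds1$survey), as.data.frame(ds2$survey))
  # detection_rate = 1: every encounter recorded, so the survey total
  # equals the summed drawn (true) abundances
  cfgf <- sim_config(n_species = 15, n_transects = c(forest = 1),
                     detection_rate = 1, seed = 13)
  tree <- simulate_tree(cfgf)
  traits <- simulate_traits(tree, cfgf)
  sv <- simulate_survey(tree, traits, cfgf)
  truth <- attr(sv, "truth")
  expect_equal(sum(sv$count), sum(truth$true_total))
  tot <- tapply(sv$count, sv$species_id, sum)
  expect_equal(as.numeric(tot[names(tot)]),
               as.numeric(truth$true_total[names(tot)]))
})

test_that("habitat filtering concentrates communities on the trait axis", {
  # neutral: occupancy unrelated to z; strong filtering: habitat
  # communities sit near their optimum
  spread <- function(strength, seed) {
    cfg <- sim_config(n_species = 80, filtering_strength = strength,
                      n_transects = c(urban = 3, farmland = 3, forest = 3,
                                      wetland = 3), seed = seed)
    ds <- simulate_dataset(cfg)
    z <- attr(ds$survey, "truth")$z
    comm <- build_community_matrix(ds$survey, "habitat")
    mean(vapply(colnames(comm), function(h) {
      pres <- rownames(comm)[comm[, h] > 0]
      sd(z[pres])
    }, numeric(1)), na.rm = TRUE)
  }
  s0 <- mean(vapply(1:5, function(s) spread(0, 400 + s), numeric(1)))
  s10 <- mean(vapply(1:5, function(s) spread(10, 400 + s), numeric(1)))
  expect_lt(s10, s0)
})
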