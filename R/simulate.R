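#' Simulation configuration
#'
#' Bundles all parameters of the synthetic survey generator. Defaults
#' emulate a year-round airport survey: a 148-species regional pool, 17
#' transects spread over four habitats, four seasonal visits, strongly
#' right-skewed species abundances, traits with phylogenetic signal, and
#' moderate habitat filtering.
#'
#' @param n_species size of the regional species pool (>= 2).
#' @param n_transects named integer vector: transects per habitat (names
#'   from the habitat vocabulary). Default c(urban = 3, farmland = 5,
#'   forest = 6, wetland = 3), totalling 17.
#' @param birth_rate Yule speciation rate (> 0).
#' @param trait_signal Brownian-motion variance per unit branch length for
#'   the continuous traits; 0 gives identical traits (no signal).
#' @param filtering_strength strength of habitat filtering on the
#'   composite trait axis; 0 = neutral assembly (occurrence independent of
#'   traits).
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   per-species expected individuals per transect-season cell.
#' @param detection_rate probability-scale thinning of expected counts,
#'   in (0, 1].
#' @param flock_prob success probability of the zero-truncated geometric
#'   flock-size distribution (smaller = larger flocks).
#' @param inside_fraction fraction of species that use the airport
#'   interior (get inside-zone records).
#' @param seed master integer seed; mandatory.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 148,
                       n_transects = c(urban = 3, farmland = 5,
                                       forest = 6, wetland = 3),
                       birth_rate = 1,
                       trait_signal = 1,
                       filtering_strength = 1.5,
                       abundance_meanlog = -1.2,
                       abundance_sdlog = 2,
                       detection_rate = 0.8,
                       flock_prob = 0.4,
                       inside_fraction = 0.2,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_species < 2) abort("n_species must be >= 2")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  if (trait_signal < 0) abort("trait_signal must be >= 0")
  if (filtering_strength < 0) abort("filtering_strength must be >= 0")
  if (detection_rate <= 0 || detection_rate > 1)
    abort("detection_rate must be in (0, 1]")
  if (flock_prob <= 0 || flock_prob > 1) abort("flock_prob must be in (0, 1]")
  if (inside_fraction < 0 || inside_fraction > 1)
    abort("inside_fraction must be in [0, 1]")
  bad <- setdiff(names(n_transects), HABITATS)
  if (length(bad)) abort("unknown habitat in n_transects: ", bad[1])
  if (any(n_transects < 1)) abort("each listed habitat needs >= 1 transect")
  structure(list(n_species = as.integer(n_species),
                 n_transects = n_transects, birth_rate = birth_rate,
                 trait_signal = trait_signal,
                 filtering_strength = filtering_strength,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 detection_rate = detection_rate, flock_prob = flock_prob,
                 inside_fraction = inside_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Standard constant-rate pure-birth process: starting from two lineages,
#' the waiting time to the next speciation at k extant lineages is
#' exponential with rate \code{birth_rate * k}, and a uniformly chosen
#' lineage splits; once the target tip count is reached the tree is cut at
#' the time the next speciation would have occurred, giving an ultrametric
#' tree with positive pendant branches. Deterministic given the config
#' seed.
#'
#' @param config a \code{sim_config}.
#' @return \code{phylo} with \code{n_species} tips labelled sp001, sp002, ...
#' @export
simulate_tree <- function(config) {
  n <- config$n_species
  if (n < 2) abort("n_species must be >= 2")
  set.seed(config$seed + 1L)
  b <- config$birth_rate
  # birth times of splits; lineage bookkeeping as a growing edge list
  # node ids: tips 1..n, internals n+1.. (root n+1)
  parent <- integer(0); child <- integer(0); btime <- numeric(0)
  # active lineages: parent node id and time that lineage started
  act_parent <- c(n + 1L, n + 1L)
  act_start <- c(0, 0)
  t_now <- 0
  next_internal <- n + 2L
  while (length(act_parent) < n) {
    k <- length(act_parent)
    t_now <- t_now + stats::rexp(1, rate = b * k)
    i <- sample.int(k, 1)
    # lineage i speciates: becomes internal node, spawns two lineages
    parent <- c(parent, act_parent[i])
    child <- c(child, next_internal)
    btime <- c(btime, t_now - act_start[i])
    act_parent <- c(act_parent[-i], next_internal, next_internal)
    act_start <- c(act_start[-i], t_now, t_now)
    next_internal <- next_internal + 1L
  }
  # extend all lineages to the moment the (n+1)-th speciation would occur,
  # so pendant branches are positive; root-to-tip depth is then a sum of
  # Exp(birth_rate * k) waits for k = 2..n
  t_now <- t_now + stats::rexp(1, rate = b * n)
  tip_order <- sample.int(n)   # random tip placement
  for (i in seq_along(act_parent)) {
    parent <- c(parent, act_parent[i])
    child <- c(child, tip_order[i])
    btime <- c(btime, t_now - act_start[i])
  }
  tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                       edge.length = btime,
                       tip.label = sprintf("sp%03d", seq_len(n)),
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

DIET_STATES <- c("carnivore", "granivore", "insectivore", "omnivore")
STRATUM_STATES <- c("ground", "understory", "canopy", "aerial")

#' Simulate functional traits on a phylogeny
#'
#' Continuous traits (log body mass and log hand-wing index) evolve by
#' correlated Brownian motion with variance scaled by \code{trait_signal}
#' per unit branch length from fixed root states; the evolutionary
#' correlation between the two is 0.7, mimicking the allometric
#' mass-flight-morphology relationship of real birds. The categorical
#' traits (diet, vertical stratum) evolve by a slow symmetric 4-state
#' Markov process (phylogenetically conserved). With
#' \code{trait_signal = 0} every species carries the root state.
#' Deterministic given the config seed.
#'
#' @param tree \code{phylo} from \code{\link{simulate_tree}}.
#' @param config a \code{sim_config}.
#' @return \code{trait_table} covering all tips.
#' @export
simulate_traits <- function(tree, config) {
  set.seed(config$seed + 2L)
  sig <- sqrt(config$trait_signal)
  rho <- 0.7   # evolutionary mass-HWI correlation
  x <- ape::rTraitCont(tree, model = "BM", sigma = sig * 0.6,
                       root.value = 0)
  y <- ape::rTraitCont(tree, model = "BM", sigma = sig * 0.35,
                       root.value = 0)
  log_mass <- log(80) + x
  log_hwi <- log(25) + rho * (0.35 / 0.6) * x + sqrt(1 - rho^2) * y
  # conserved categorical traits: ~0.75 expected state changes root-to-tip
  depth <- max(ape::node.depth.edgelength(tree))
  rate <- if (depth > 0) 0.25 / depth else 0.25
  d <- ape::rTraitDisc(tree, model = "ER", k = 4, rate = rate,
                       states = DIET_STATES)
  diet <- stats::setNames(as.character(d), names(d))
  s <- ape::rTraitDisc(tree, model = "ER", k = 4, rate = rate,
                       states = STRATUM_STATES)
  stratum <- stats::setNames(as.character(s), names(s))
  sp <- tree$tip.label
  as_trait_table(data.frame(species_id = sp,
                            body_mass = exp(as.numeric(log_mass[sp])),
                            hwi = exp(as.numeric(log_hwi[sp])),
                            diet = diet[sp], stratum = stratum[sp],
                            stringsAsFactors = FALSE))
}

#' Simulate per-species flight, flocking and zone attributes
#'
#' Assigns each species a preferred flight-height band (heavier species
#' biased toward higher bands via the body-mass rank, with most species
#' in the lowest band, as in field communities dominated by small
#' passerines) with a distance-decay distribution over neighbouring
#' bands; a species-specific flocking tendency (lognormal across species,
#' so most species are near-solitary and a few form large flocks); and
#' flags a configurable fraction of species as users of the airport
#' interior. Deterministic given the config seed.
#'
#' @param traits \code{trait_table}.
#' @param config a \code{sim_config}.
#' @return data frame with species_id, pref_band, flock_p (per-encounter
#'   geometric parameter), inside_user; attribute \code{"band_probs"}
#'   holds the species x band probability matrix.
#' @export
simulate_risk_attributes <- function(traits, config) {
  set.seed(config$seed + 3L)
  n <- nrow(traits)
  rank01 <- (rank(traits$body_mass, ties.method = "first") - 0.5) / n
  # most species in the 0-5 m band; the heaviest spread upward
  pref <- findInterval(rank01, c(0.70, 0.85, 0.93, 0.975)) + 1L
  probs <- t(vapply(pref, function(b) {
    w <- 0.3^abs(seq_len(5) - b)
    w / sum(w)
  }, numeric(5)))
  colnames(probs) <- HEIGHT_BANDS
  rownames(probs) <- traits$species_id
  # mean extra flock size = baseline (1/flock_prob - 1) scaled by a
  # right-skewed species factor
  gfac <- stats::rlnorm(n, 0, 1)
  extra <- (1 / config$flock_prob - 1) * gfac
  flock_p <- 1 / (1 + extra)
  n_in <- round(config$inside_fraction * n)
  inside <- rep(FALSE, n)
  if (n_in > 0) inside[sample.int(n, n_in)] <- TRUE
  out <- data.frame(species_id = traits$species_id,
                    pref_band = HEIGHT_BANDS[pref], flock_p = flock_p,
                    inside_user = inside, stringsAsFactors = FALSE)
  attr(out, "band_probs") <- probs
  out
}

# habitat optima sit at these quantiles of the realized composite trait
# axis, so each habitat's niche window is equally populated regardless of
# how the simulated traits happen to be distributed
HABITATS4 <- c("urban", "farmland", "forest", "wetland")
HABITAT_QUANTILES <- c(urban = 0.15, farmland = 0.38, forest = 0.62,
                       wetland = 0.85)

#' Simulate a seasonal transect survey
#'
#' Assembly model: each habitat has a latent optimum on the standardized
#' composite trait axis z (the standardized sum of scaled log body mass
#' and scaled hand-wing index), placed at the 15/38/62/85 percent
#' quantiles of the realized axis so every niche window is populated.
#' Suitability decays as \code{exp(-filtering_strength * (z - opt_h)^2)}
#' and is normalized within each habitat to a constant expected occupancy
#' (40 percent of the pool, capped at 1) — a fixed species capacity, so
#' filtering redistributes membership toward suited species rather than
#' emptying the habitat. Species are included by one Bernoulli draw per
#' species and habitat, so occurrence — not abundance — carries the
#' filtering signal. Included species draw
#' a lognormal abundance scale \code{lambda} (expected individuals per
#' transect-season cell), independent of their traits. Encounters per
#' cell are Poisson with mean \code{lambda / mean_flock}, each carrying a
#' zero-truncated geometric flock size with species-specific mean, so
#' expected individuals per cell are \code{lambda}; each encounter is
#' then detected with probability \code{detection_rate} as a whole flock.
#' Each detected encounter becomes one record with a flight-height band
#' drawn from the species' band distribution and a zone flag from its
#' airport-use attribute (an interior-using species' first record is
#' forced inside, so the zone coefficient is determined by the flag).
#' With \code{filtering_strength = 0} occurrence is independent of traits
#' (neutral assembly). Deterministic given the config seed.
#'
#' @param tree \code{phylo} over the pool.
#' @param traits \code{trait_table} covering all tips.
#' @param config a \code{sim_config}.
#' @return \code{survey_table}; attribute \code{"truth"} holds the latent
#'   quantities (composite axis z, habitat optima and weights, abundance
#'   scales, risk attributes, and per-species true individual totals
#'   before detection thinning).
#' @export
simulate_survey <- function(tree, traits, config) {
  if (!all(tree$tip.label %in% traits$species_id))
    abort("traits must cover all tips")
  risk_attr <- simulate_risk_attributes(traits, config)
  band_probs <- attr(risk_attr, "band_probs")
  set.seed(config$seed + 4L)
  sp <- traits$species_id
  n <- length(sp)

  zm <- as.numeric(scale(log(traits$body_mass)))
  zh <- as.numeric(scale(traits$hwi))
  if (any(!is.finite(zm))) zm <- rep(0, n)   # zero-variance trait
  if (any(!is.finite(zh))) zh <- rep(0, n)
  comp <- zm + zh
  z <- if (stats::sd(comp) > 0) as.numeric(scale(comp)) else rep(0, n)

  # species x habitat inclusion probability: suitability decays with the
  # squared standardized distance on the composite trait axis to the
  # habitat optimum (a quantile of the realized axis, so every niche
  # window is populated); probabilities are normalized so each habitat
  # hosts a constant expected fraction of the pool (a fixed species
  # capacity) — filtering redistributes membership toward suited species
  # rather than emptying the habitat
  occupancy <- 0.4
  optima <- stats::quantile(z, HABITAT_QUANTILES, names = FALSE)
  names(optima) <- HABITATS4
  w <- vapply(HABITATS4, function(h) {
    raw <- exp(-config$filtering_strength * (z - optima[[h]])^2)
    pmin(1, raw * occupancy * n / sum(raw))
  }, numeric(n))
  included <- matrix(stats::runif(length(w)) < w, nrow(w), ncol(w),
                     dimnames = dimnames(w))
  lambda <- stats::rlnorm(n, config$abundance_meanlog,
                          config$abundance_sdlog)

  habitats <- names(config$n_transects)
  transects <- unlist(lapply(habitats, function(h)
    paste0(h, "_t", seq_len(config$n_transects[[h]]))), use.names = FALSE)
  t_habitat <- rep(habitats, times = config$n_transects[habitats])

  mean_flock <- 1 / risk_attr$flock_p   # mean of the zero-truncated geometric
  rows <- vector("list", 0L)
  first_inside_done <- stats::setNames(rep(FALSE, n), sp)
  true_total <- stats::setNames(rep(0L, n), sp)
  for (ti in seq_along(transects)) {
    h <- t_habitat[ti]
    for (season in SEASONS) {
      n_enc <- stats::rpois(n, lambda * included[, h] / mean_flock)
      for (si in which(n_enc > 0)) {
        for (e in seq_len(n_enc[si])) {
          flock <- stats::rgeom(1, risk_attr$flock_p[si]) + 1L
          true_total[si] <- true_total[si] + flock
          if (stats::runif(1) > config$detection_rate) next
          band <- sample(HEIGHT_BANDS, 1, prob = band_probs[si, ])
          zone <- if (risk_attr$inside_user[si]) {
            if (!first_inside_done[[si]]) {
              first_inside_done[[si]] <- TRUE
              "inside"
            } else if (stats::runif(1) < 0.5) "inside" else "outside"
          } else "outside"
          rows[[length(rows) + 1L]] <- data.frame(
            species_id = sp[si], transect_id = transects[ti], habitat = h,
            season = season, count = as.integer(flock), height_band = band,
            zone = zone, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    abort("simulation produced no detections; increase abundance or detection_rate")
  survey <- as_survey_table(do.call(rbind, rows))
  attr(survey, "truth") <- list(z = stats::setNames(z, sp),
                                optima = optima, weights = w,
                                included = included,
                                lambda = stats::setNames(lambda, sp),
                                risk_attr = risk_attr,
                                true_total = true_total)
  survey
}

#' Default habitat-area table for simulations
#'
#' Plausible areas (hectares) for the four habitat types within an
#' ~8 km-radius survey circle (~20,000 ha), forest-dominated.
#'
#' @return \code{habitat_areas} vector.
#' @export
default_habitat_areas <- function() {
  as_habitat_areas(c(urban = 2700, farmland = 6000, forest = 9400,
                     wetland = 2000))
}

#' Simulate a complete dataset
#'
#' Tree, traits, survey, and habitat areas in one call — the synthetic
#' counterpart of the four user-supplied inputs.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{tree}, \code{traits}, \code{survey},
#'   \code{areas}, \code{config}.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_tree(config)
  traits <- simulate_traits(tree, config)
  survey <- simulate_survey(tree, traits, config)
  list(tree = tree, traits = traits, survey = survey,
       areas = default_habitat_areas(), config = config)
}
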