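#' Relative abundance index N
#'
#' \code{N = 100 * individuals of the species / individuals of the most
#' abundant species}. The most abundant species scores 100 by
#' construction.
#'
#' @param totals named vector of per-species individual totals.
#' @return named numeric vector of N values (0-100].
#' @export
abundance_index <- function(totals) {
  if (length(totals) == 0L || max(totals) <= 0) abort("all-zero abundances")
  100 * totals / max(totals)
}

#' Relative flock-size index G
#'
#' Average flock size of a species = total individuals / number of
#' encounters (detection records); \code{G = 100 * flock / max flock}.
#' Every record in the survey table is one encounter, so a flock of k
#' birds is one row with count k.
#'
#' @param survey a \code{survey_table}.
#' @return data frame with species_id, encounters, individuals,
#'   flock_size, G.
#' @export
flock_index <- function(survey) {
  enc <- table(survey$species_id)
  ind <- tapply(survey$count, survey$species_id, sum)
  sp <- names(enc)
  flock <- as.numeric(ind[sp]) / as.numeric(enc)
  data.frame(species_id = sp, encounters = as.integer(enc),
             individuals = as.integer(ind[sp]), flock_size = flock,
             G = 100 * flock / max(flock), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Spatial distribution index S
#'
#' Occupied area of a species = sum of the areas of the habitat types in
#' which it was recorded (each habitat counted once);
#' \code{S = 100 * occupied / total survey area}.
#'
#' @param survey a \code{survey_table}.
#' @param areas \code{habitat_areas} covering every habitat in the survey.
#' @return named numeric vector of S values (0-100].
#' @export
spatial_index <- function(survey, areas) {
  missing <- setdiff(unique(survey$habitat), names(areas))
  if (length(missing)) abort("habitat missing from area table: ",
                             paste(missing, collapse = ", "))
  total <- sum(areas)
  occ <- tapply(survey$habitat, survey$species_id,
                function(h) sum(areas[unique(h)]))
  stats::setNames(100 * as.numeric(occ) / total, names(occ))
}

#' Body-mass index W
#'
#' \code{W = 100 * species body mass / maximum body mass} among the
#' assessed species.
#'
#' @param traits \code{trait_table}.
#' @param species species to assess (default all in the table).
#' @return named numeric vector of W values (0-100].
#' @export
mass_index <- function(traits, species = NULL) {
  species <- species %||% traits$species_id
  miss <- setdiff(species, traits$species_id)
  if (length(miss)) abort("species missing body mass: ",
                          paste(miss, collapse = ", "))
  m <- traits$body_mass[match(species, traits$species_id)]
  stats::setNames(100 * m / max(m), species)
}

# coefficient for each height band
HEIGHT_COEF <- c(B0_5 = 0.1, B5_30 = 0.5, B30_50 = 1.0,
                 B50_100 = 0.5, B100plus = 0.1)

#' Flight-height coefficient H
#'
#' Bands score 0.1 (0-5 m), 0.5 (5-30 m), 1.0 (30-50 m), 0.5 (50-100 m),
#' 0.1 (> 100 m) — highest where overlap with approach/departure altitudes
#' is greatest. A species observed in several bands gets the coefficient
#' of its modal band (most records); ties are broken toward the larger
#' coefficient.
#'
#' @param survey a \code{survey_table}.
#' @param allow_drop if TRUE, species whose records all lack a height band
#'   are dropped with a message instead of raising an error.
#' @return named numeric vector of H per species.
#' @export
height_coefficient <- function(survey, allow_drop = FALSE) {
  sp <- sort(unique(survey$species_id))
  H <- vapply(sp, function(s) {
    bands <- survey$height_band[survey$species_id == s]
    bands <- bands[!is.na(bands)]
    if (length(bands) == 0L) return(NA_real_)
    tab <- table(bands)
    modal <- names(tab)[tab == max(tab)]
    max(HEIGHT_COEF[modal])
  }, numeric(1))
  bad <- names(H)[is.na(H)]
  if (length(bad)) {
    if (!allow_drop)
      abort("no height-band records for species: ",
            paste(bad, collapse = ", "),
            " (set allow_drop = TRUE to drop them)")
    message("dropping ", length(bad), " species with no height band: ",
            paste(bad, collapse = ", "))
    H <- H[!is.na(H)]
  }
  H
}

#' Activity-zone coefficient D
#'
#' 0.5 for species recorded inside the airport at least once, 0.1 for
#' species recorded only in the peripheral cone zone (a species seen in
#' both gets the higher value).
#'
#' @param survey a \code{survey_table}.
#' @return named numeric vector of D per species.
#' @export
zone_coefficient <- function(survey) {
  inside <- tapply(survey$zone == "inside", survey$species_id, any)
  stats::setNames(ifelse(as.logical(inside), 0.5, 0.1), names(inside))
}

#' Risk-tier label for a risk value
#'
#' Tiers partition the risk axis: R >= 25 extremely high, 15 <= R < 25
#' high, 5 <= R < 15 moderate, R < 5 low.
#'
#' @param R numeric risk value(s).
#' @return factor with levels extremely_high, high, moderate, low.
#' @export
risk_tier <- function(R) {
  lab <- ifelse(R >= 25, "extremely_high",
         ifelse(R >= 15, "high",
         ifelse(R >= 5, "moderate", "low")))
  factor(lab, levels = c("extremely_high", "high", "moderate", "low"))
}

#' Per-species bird-strike risk assessment
#'
#' Combines the four importance components and the two behavioural
#' coefficients into the composite risk value:
#' \deqn{IV = (N + G + S + W)/4, \quad F = (H + D)/2, \quad R = IV \times F,}
#' and classifies each species into the four risk tiers. Species present
#' in the survey but missing traits or height bands raise an error unless
#' \code{allow_drop = TRUE}, in which case they are removed with a
#' message (indices are then renormalized over the retained species).
#'
#' @param survey a \code{survey_table}.
#' @param traits \code{trait_table} with body masses.
#' @param areas \code{habitat_areas}.
#' @param allow_drop drop species with missing traits/height bands.
#' @return data frame, one row per species: N, G, S, W, IV, H, D, F, R,
#'   tier; ordered by decreasing R.
#' @export
assess_risk <- function(survey, traits, areas, allow_drop = FALSE) {
  sp <- sort(unique(survey$species_id))
  miss_tr <- setdiff(sp, traits$species_id)
  if (length(miss_tr)) {
    if (!allow_drop)
      abort("species missing from trait table: ",
            paste(miss_tr, collapse = ", "),
            " (set allow_drop = TRUE to drop them)")
    message("dropping ", length(miss_tr), " species without traits: ",
            paste(miss_tr, collapse = ", "))
  }
  H <- height_coefficient(survey, allow_drop = allow_drop)
  keep <- setdiff(intersect(sp, names(H)),
                  if (length(miss_tr)) miss_tr else character(0))
  if (length(keep) == 0L) abort("no species left to assess")
  survey <- survey[survey$species_id %in% keep, , drop = FALSE]
  class(survey) <- c("survey_table", "data.frame")

  totals <- tapply(survey$count, survey$species_id, sum)
  N <- abundance_index(stats::setNames(as.numeric(totals), names(totals)))
  fl <- flock_index(survey)
  G <- stats::setNames(fl$G, fl$species_id)
  S <- spatial_index(survey, areas)
  W <- mass_index(traits, sort(names(N)))
  H <- H[names(N)]
  D <- zone_coefficient(survey)[names(N)]
  G <- G[names(N)]; S <- S[names(N)]; W <- W[names(N)]

  IV <- (N + G + S + W) / 4
  F_ <- (H + D) / 2
  R <- IV * F_
  out <- data.frame(species_id = names(N), N = as.numeric(N),
                    G = as.numeric(G), S = as.numeric(S), W = as.numeric(W),
                    IV = as.numeric(IV), H = as.numeric(H),
                    D = as.numeric(D), F = as.numeric(F_),
                    R = as.numeric(R), tier = risk_tier(as.numeric(R)),
                    stringsAsFactors = FALSE)
  out[order(-out$R, out$species_id), , drop = FALSE]
}

#' Risk-tier summary
#'
#' Counts and percentage shares (rounded half-up to 2 decimals) of species
#' per risk tier.
#'
#' @param assessment result of \code{\link{assess_risk}}, or a named
#'   vector/table of tier counts (names among the four tier labels).
#' @return data frame with tier, count, share.
#' @export
risk_report <- function(assessment) {
  lev <- levels(risk_tier(0))
  counts <- if (is.data.frame(assessment)) {
    table(factor(assessment$tier, levels = lev))
  } else {
    bad <- setdiff(names(assessment), lev)
    if (length(bad)) abort("unknown tier label: ", bad[1])
    cnt <- stats::setNames(rep(0, length(lev)), lev)
    cnt[names(assessment)] <- as.numeric(assessment)
    cnt
  }
  counts <- as.numeric(counts[lev])
  data.frame(tier = lev, count = counts,
             share = percent_share(counts, sum(counts)),
             stringsAsFactors = FALSE)
}
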