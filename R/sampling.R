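#' Abundance frequency counts of an assemblage
#'
#' Tallies, from a vector of species abundances, the quantities the
#' nonparametric richness machinery runs on: observed richness
#' \code{S_obs}, total individuals \code{n}, and \code{f[k]} = number of
#' species with abundance exactly k. Zero-abundance species are ignored.
#'
#' @param x non-negative integer abundance vector (one assemblage).
#' @return list with \code{S_obs}, \code{n}, \code{f} (named integer vector
#'   indexed by abundance class as character), and helpers \code{f1},
#'   \code{f2}.
#' @export
frequency_counts <- function(x) {
  if (any(x < 0) || any(x != round(x))) abort("abundances must be non-negative integers")
  x <- x[x > 0]
  if (length(x) == 0L) abort("empty assemblage")
  tab <- table(x)
  f <- stats::setNames(as.integer(tab), names(tab))
  fk <- function(k) if (as.character(k) %in% names(f)) f[[as.character(k)]] else 0L
  list(S_obs = length(x), n = sum(x), f = f, f1 = fk(1), f2 = fk(2),
       abundances = as.integer(x))
}

#' Chao1 abundance-based richness estimator
#'
#' \code{S_obs + f1^2 / (2 f2)} when doubletons exist, otherwise the
#' bias-corrected \code{S_obs + f1 (f1 - 1) / 2}.
#'
#' @param x abundance vector for one assemblage.
#' @return estimated asymptotic species richness.
#' @export
chao1 <- function(x) {
  fc <- frequency_counts(x)
  if (fc$f2 > 0) fc$S_obs + fc$f1^2 / (2 * fc$f2)
  else fc$S_obs + fc$f1 * (fc$f1 - 1) / 2
}

#' Chao2 incidence-based richness estimator
#'
#' Operates on species-by-sampling-unit incidence: \code{q1}/\code{q2} are
#' the numbers of species occurring in exactly one/two units, \code{R} the
#' number of units. Applies the standard \code{(R-1)/R} small-sample factor
#' to the rarity term; when \code{q2 = 0} the bias-corrected
#' \code{q1 (q1 - 1) / 2} form is used.
#'
#' @param incidence species-by-unit matrix (abundances or 0/1), or a
#'   logical matrix.
#' @return estimated asymptotic species richness.
#' @export
chao2 <- function(incidence) {
  inc <- incidence > 0
  if (is.null(dim(inc))) abort("incidence must be a species-by-unit matrix")
  R <- ncol(inc)
  if (R < 2) abort("need at least 2 sampling units")
  units_per_sp <- rowSums(inc)
  units_per_sp <- units_per_sp[units_per_sp > 0]
  S_obs <- length(units_per_sp)
  q1 <- sum(units_per_sp == 1)
  q2 <- sum(units_per_sp == 2)
  corr <- (R - 1) / R
  if (q2 > 0) S_obs + corr * q1^2 / (2 * q2)
  else S_obs + corr * q1 * (q1 - 1) / 2
}

#' Estimated sample coverage of an assemblage
#'
#' The Good-Turing style estimate of the proportion of individuals in the
#' assemblage belonging to species already detected:
#' \deqn{\hat C = 1 - (f_1/n) \cdot (n-1) f_1 / ((n-1) f_1 + 2 f_2).}
#' Equals 1 when there are no singletons. The abundance-based form is
#' computed (per-assemblage column of a community matrix).
#'
#' @param x abundance vector for one assemblage.
#' @return coverage estimate in [0, 1].
#' @export
sample_coverage <- function(x) {
  fc <- frequency_counts(x)
  if (fc$f1 == 0) return(1)
  if (fc$n == 1) {
    warning("coverage undefined for n = 1; returning formula limit 1")
    return(1)
  }
  a <- (fc$n - 1) * fc$f1
  1 - (fc$f1 / fc$n) * a / (a + 2 * fc$f2)
}

#' Rarefied expected species richness
#'
#' Expected number of species in a random subsample of \code{m} individuals
#' (without replacement):
#' \deqn{S(m) = S_{obs} - \sum_i \binom{n - x_i}{m} / \binom{n}{m},}
#' evaluated through log-gamma (via \code{lchoose}) so large \code{n} do not
#' overflow. \code{m > n} is routed to \code{\link{extrapolated_richness}}.
#'
#' @param x abundance vector.
#' @param m subsample size(s), positive integers.
#' @return expected richness, same length as \code{m}.
#' @export
rarefied_richness <- function(x, m) {
  fc <- frequency_counts(x)
  n <- fc$n
  xs <- fc$abundances
  vapply(m, function(mi) {
    if (mi < 1) abort("m must be >= 1")
    if (mi > n) return(extrapolated_richness(x, mi))
    # species with n - x_i < m cannot be missed entirely
    keep <- (n - xs) >= mi
    miss <- if (any(keep)) sum(exp(lchoose(n - xs[keep], mi) - lchoose(n, mi))) else 0
    fc$S_obs - miss
  }, numeric(1))
}

#' Extrapolated expected species richness
#'
#' Chao1-anchored extrapolation beyond the observed sample size:
#' \deqn{S(n + m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m^*}]}
#' with \eqn{\hat f_0 = \mathrm{Chao1} - S_{obs}} and \eqn{m^* = m - n}.
#' With no singletons the curve is flat at \code{S_obs}; as
#' \eqn{m^* \to \infty} it asymptotes to Chao1.
#'
#' @param x abundance vector.
#' @param m target sample size(s), \code{> n}.
#' @return expected richness, same length as \code{m}.
#' @export
extrapolated_richness <- function(x, m) {
  fc <- frequency_counts(x)
  n <- fc$n
  vapply(m, function(mi) {
    if (mi <= n) return(rarefied_richness(x, mi))
    if (fc$f1 == 0) return(as.numeric(fc$S_obs))
    f0 <- chao1(x) - fc$S_obs
    if (f0 <= 0) return(as.numeric(fc$S_obs))
    mstar <- mi - n
    fc$S_obs + f0 * (1 - (1 - fc$f1 / (n * f0 + fc$f1))^mstar)
  }, numeric(1))
}

#' Rarefaction-extrapolation curve for one assemblage
#'
#' Convenience wrapper producing the points of a sample-size-based R/E
#' curve: interpolated below the observed sample size, the observed point
#' at \code{m = n}, extrapolated above it.
#'
#' @param x abundance vector.
#' @param m_max largest sample size (default \code{2 n}).
#' @param n_points number of curve points.
#' @return data frame with columns \code{m}, \code{richness},
#'   \code{method} ("rarefied"/"observed"/"extrapolated").
#' @export
re_curve <- function(x, m_max = NULL, n_points = 40) {
  fc <- frequency_counts(x)
  n <- fc$n
  m_max <- m_max %||% (2L * n)
  m <- unique(sort(c(1L, round(seq(1, m_max, length.out = n_points)), n)))
  data.frame(m = m,
             richness = rarefied_richness(x, m),
             method = ifelse(m < n, "rarefied",
                             ifelse(m == n, "observed", "extrapolated")),
             stringsAsFactors = FALSE)
}

#' Species accumulation curve over sampling units
#'
#' Mean and standard deviation of cumulative species richness as sampling
#' units are added in random order. When the number of units is <= 7 all
#' orderings are enumerated exhaustively; otherwise \code{n_perm} random
#' permutations are used (deterministic given \code{seed}).
#'
#' @param comm species-by-unit matrix (columns are sampling units).
#' @param n_perm number of random orderings (ignored when exhaustive).
#' @param seed integer seed for the permutations.
#' @return data frame with columns \code{units}, \code{mean_richness},
#'   \code{sd_richness}; the last row always equals total observed
#'   richness with sd 0.
#' @export
accumulation_curve <- function(comm, n_perm = 100, seed = 1) {
  if (is.null(dim(comm)) || ncol(comm) < 2) abort("need >= 2 sampling units")
  inc <- comm > 0
  R <- ncol(inc)
  orderings <- if (R <= 7) {
    perms <- all_permutations(R)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(R))
  }
  acc <- vapply(orderings, function(ord) {
    seen <- rep(FALSE, nrow(inc))
    vapply(ord, function(j) {
      seen <<- seen | inc[, j]
      sum(seen)
    }, numeric(1))
  }, numeric(R))
  data.frame(units = seq_len(R),
             mean_richness = rowMeans(acc),
             sd_richness = apply(acc, 1, stats::sd))
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in practice
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Sampling-adequacy summary table
#'
#' Per-assemblage observed richness, abundance, estimated coverage and
#' Chao1 — the layout of a survey-adequacy report by habitat or season.
#'
#' @param comm community matrix from \code{\link{build_community_matrix}}.
#' @return data frame, one row per assemblage.
#' @export
adequacy_table <- function(comm) {
  out <- data.frame(
    assemblage = colnames(comm),
    species = colSums(comm > 0),
    abundance = colSums(comm),
    coverage = apply(comm, 2, sample_coverage),
    chao1 = apply(comm, 2, chao1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
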