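#' Richness-constrained community randomization
#'
#' Draws a random community of the same richness as the observed one by
#' sampling species uniformly without replacement from the regional pool —
#' the label-shuffle null applied to the functional/phylogenetic distance
#' matrices, holding species richness constant.
#'
#' @param community character vector (observed species) or an integer
#'   richness.
#' @param pool character vector: the regional species pool.
#' @return character vector of sampled species, same length as the
#'   community richness.
#' @export
randomize_community <- function(community, pool) {
  n <- if (is.numeric(community)) as.integer(community)
       else length(unique(community))
  if (n > length(pool)) abort("community larger than pool")
  pool[sample.int(length(pool), n)]
}

#' Null distribution of a diversity metric
#'
#' Scores the observed community and \code{n_iter} richness-matched random
#' communities (drawn from the pool) with one of FD, PD, MFD, MPD, using
#' the same precomputed structures throughout. Deterministic given
#' \code{seed}.
#'
#' @param metric one of \code{"FD"}, \code{"PD"}, \code{"MFD"},
#'   \code{"MPD"}.
#' @param community character vector of observed species.
#' @param pool character vector, the regional pool (all species observed
#'   anywhere in the study); must contain the community.
#' @param structures result of \code{\link{community_structures}}.
#' @param n_iter number of randomizations (default 999).
#' @param seed integer seed.
#' @return object of class \code{null_distribution}: list with
#'   \code{metric}, \code{M_obs}, \code{null} (length \code{n_iter}),
#'   \code{M_exp}, \code{SD_exp}, \code{n_iter}, \code{seed}.
#' @export
null_distribution <- function(metric = c("FD", "PD", "MFD", "MPD"),
                              community, pool, structures,
                              n_iter = 999, seed = 1) {
  metric <- match.arg(metric)
  community <- unique(as.character(community))
  pool <- unique(as.character(pool))
  if (!all(community %in% pool)) abort("community species missing from pool")
  if (!all(pool %in% structures$species))
    abort("pool species missing from structures")
  n <- length(community)
  if (metric %in% c("MFD", "MPD") && n < 2)
    abort("MFD/MPD require a community of at least 2 species")

  set.seed(seed)
  npool <- length(pool)
  # indicator matrix of the null communities, pool species x n_iter
  V <- vapply(seq_len(n_iter), function(i) {
    v <- logical(npool)
    v[sample.int(npool, n)] <- TRUE
    v
  }, logical(npool))
  rownames(V) <- pool

  score <- metric_scorer(metric, structures)
  M_obs <- score(structure(pool %in% community, names = pool), V = NULL)
  null <- score(NULL, V = V)
  list_out <- list(metric = metric, M_obs = M_obs, null = null,
                   M_exp = mean(null), SD_exp = stats::sd(null),
                   n_iter = n_iter, seed = seed)
  class(list_out) <- "null_distribution"
  list_out
}

# Returns a closure scoring either one indicator vector (over `pool`) or a
# pool x n_iter indicator matrix V, vectorized with one matrix product.
metric_scorer <- function(metric, structures) {
  if (metric %in% c("FD", "PD")) {
    tr <- if (metric == "FD") structures$dendro else structures$tree
    M <- edge_tip_incidence(tr)
    elen <- tr$edge.length
    tips <- colnames(M)
    function(v, V = NULL) {
      if (is.null(V)) {
        pres <- tips %in% names(v)[v]
        return(subtree_length(M, elen, pres))
      }
      # expand pool-indexed indicators to tip order of the tree
      Vt <- matrix(FALSE, length(tips), ncol(V))
      idx <- match(rownames(V), tips)
      Vt[idx[!is.na(idx)], ] <- V[!is.na(idx), ]
      cnt <- M %*% Vt
      ncomm <- colSums(Vt)
      vapply(seq_len(ncol(Vt)), function(j) {
        keep <- cnt[, j] >= 1 & cnt[, j] < ncomm[j]
        sum(elen[keep])
      }, numeric(1))
    }
  } else {
    D <- if (metric == "MFD") structures$fdist else structures$pdist
    function(v, V = NULL) {
      if (is.null(V)) {
        sp <- names(v)[v]
        return(mean_pairwise_distance(D, sp))
      }
      Dp <- D[rownames(V), rownames(V)]
      q <- colSums(V * (Dp %*% V))    # sum over ordered pairs per column
      n <- colSums(V)
      q / (n * (n - 1))
    }
  }
}

#' Standardized effect size from a null distribution
#'
#' \deqn{SES = (M_{obs} - M_{exp}) / SD_{exp}.} Negative values indicate
#' functional or phylogenetic clustering (environmental filtering),
#' positive values overdispersion (competitive exclusion). When the null
#' distribution is degenerate (SD_exp = 0) the SES is undefined and the
#' interpretation is "indeterminate".
#'
#' @param nd a \code{null_distribution}.
#' @return list with \code{ses} (numeric or NA), \code{interpretation}
#'   (\code{"clustered"}, \code{"overdispersed"}, or
#'   \code{"indeterminate"}), and the inputs \code{M_obs}, \code{M_exp},
#'   \code{SD_exp}.
#' @export
ses <- function(nd) {
  stopifnot(inherits(nd, "null_distribution"))
  if (!is.finite(nd$SD_exp) || nd$SD_exp <= 0) {
    return(list(ses = NA_real_, interpretation = "indeterminate",
                M_obs = nd$M_obs, M_exp = nd$M_exp, SD_exp = nd$SD_exp))
  }
  s <- (nd$M_obs - nd$M_exp) / nd$SD_exp
  interp <- if (s < 0) "clustered" else if (s > 0) "overdispersed"
            else "indeterminate"
  list(ses = s, interpretation = interp,
       M_obs = nd$M_obs, M_exp = nd$M_exp, SD_exp = nd$SD_exp)
}

#' SES table for every assemblage and metric
#'
#' Runs the richness-constrained null model for each assemblage (column)
#' of a community matrix and each requested metric, against the regional
#' pool (all species in the matrix by default). Assemblages with fewer
#' than 2 species are skipped for MFD/MPD with a message. Per-assemblage
#' seeds are spawned deterministically from the master seed, so results do
#' not depend on execution order.
#'
#' @param comm community matrix.
#' @param structures result of \code{\link{community_structures}}.
#' @param metrics subset of c("FD", "PD", "MFD", "MPD").
#' @param pool regional pool (default: all species of \code{comm}).
#' @param n_iter randomizations per null (default 999).
#' @param seed master integer seed.
#' @return data frame with columns assemblage, metric, M_obs, M_exp,
#'   SD_exp, SES, interpretation, plus assemblage metadata.
#' @export
ses_table <- function(comm, structures,
                      metrics = c("FD", "PD", "MFD", "MPD"),
                      pool = NULL, n_iter = 999, seed = 1) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  sp <- rownames(comm)
  pool <- pool %||% sp
  rows <- list()
  for (ai in seq_len(ncol(comm))) {
    a <- colnames(comm)[ai]
    pres <- sp[comm[, ai] > 0]
    for (mi in seq_along(metrics)) {
      metric <- metrics[mi]
      if (metric %in% c("MFD", "MPD") && length(pres) < 2) {
        message("skipping ", metric, " for assemblage '", a,
                "': fewer than 2 species")
        next
      }
      sub_seed <- (seed + 7919L * ai + 104729L * mi) %% .Machine$integer.max
      nd <- null_distribution(metric, pres, pool, structures,
                              n_iter = n_iter, seed = sub_seed)
      s <- ses(nd)
      rows[[length(rows) + 1L]] <- data.frame(
        assemblage = a, metric = metric, M_obs = s$M_obs, M_exp = s$M_exp,
        SD_exp = s$SD_exp, SES = s$ses, interpretation = s$interpretation,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  meta <- attr(comm, "meta")
  if (!is.null(meta)) out <- merge(meta, out, by = "assemblage", sort = TRUE)
  out
}
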