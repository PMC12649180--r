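#' Kruskal-Wallis comparison of grouped diversity values
#'
#' Rank-based omnibus test (with tie correction) across habitat or season
#' groups, delegating the statistic to \code{stats::kruskal.test}. The
#' p-value comes from the chi-squared approximation with k - 1 degrees of
#' freedom, except for very small samples (pooled n <= 8) where an exact
#' permutation p is computed by enumerating every distinct assignment of
#' the pooled values to the group sizes.
#'
#' @param groups named list of numeric vectors, one element per group.
#' @return list with \code{H}, \code{df}, \code{p_value}, \code{method}
#'   ("chi-squared" or "exact permutation"), \code{n}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) abort("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (n < 3) abort("need at least 3 observations in total")
  if (length(unique(values)) == 1L) {
    # complete ties: no rank information, H = 0 by convention
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                method = "complete ties", n = n))
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)
  if (n <= 8) {
    assigns <- group_assignments(n, sizes)
    Hs <- vapply(assigns, function(idx) {
      unname(stats::kruskal.test(values, factor(idx))$statistic)
    }, numeric(1))
    p <- mean(Hs >= H - 1e-12)
    method <- "exact permutation"
  } else {
    p <- kt$p.value
    method <- "chi-squared"
  }
  list(H = H, df = unname(kt$parameter), p_value = p, method = method, n = n)
}

# every distinct assignment of n items to groups of the given sizes;
# returns a list of integer vectors (group index per item)
group_assignments <- function(n, sizes) {
  out <- list()
  recurse <- function(remaining, g, assign) {
    if (g > length(sizes)) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    if (g == length(sizes)) {   # last group is forced
      assign[remaining] <- g
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[g], simplify = FALSE)
    for (p in picks) {
      a2 <- assign
      a2[p] <- g
      recurse(setdiff(remaining, p), g + 1L, a2)
    }
  }
  recurse(seq_len(n), 1L, integer(n))
  out
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for every pair of groups, with
#' \code{p_adj = min(1, p * number of pairs)} and significance flags at
#' the 0.05 and 0.01 levels (the "*" / "**" annotations of the usual
#' boxplot figures). Also reports the standardized statistic z from the
#' normal approximation of the rank-sum.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the flags (0.05; the stricter flag
#'   uses alpha/5 = 0.01).
#' @return data frame with group1, group2, W, z, p_raw, p_adj,
#'   significance ("", "*", or "**").
#' @export
pairwise_wilcoxon <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) abort("need >= 2 groups")
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    W <- unname(wt$statistic)
    # standardized rank-sum statistic (tie-corrected normal approximation)
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
    data.frame(group1 = nm[pr[1]], group2 = nm[pr[2]], W = W, z = z,
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out$significance <- ifelse(out$p_adj < alpha / 5, "**",
                       ifelse(out$p_adj < alpha, "*", ""))
  out
}

#' Habitat/season comparison of diversity indices
#'
#' For each diversity column, groups the per-transect (or per
#' transect-season) values by the chosen factor, runs the Kruskal-Wallis
#' omnibus test, and — only when the omnibus p < 0.05, unless
#' \code{force_posthoc} — the pairwise Bonferroni-corrected Wilcoxon
#' post hoc tests.
#'
#' @param profile data frame from \code{\link{diversity_profile}} with a
#'   grouping column present (habitat or season).
#' @param group name of the grouping column.
#' @param metrics diversity columns to test.
#' @param force_posthoc run post hoc tests regardless of the omnibus p.
#' @return list with \code{omnibus} (data frame: metric, H, df, p_value,
#'   method) and \code{posthoc} (named list of pairwise tables, possibly
#'   empty).
#' @export
compare_groups <- function(profile, group = "habitat",
                           metrics = c("abundance", "SR", "FD", "PD",
                                       "MFD", "MPD"),
                           force_posthoc = FALSE) {
  if (!group %in% names(profile)) abort("no column '", group, "' in profile")
  metrics <- intersect(metrics, names(profile))
  omnibus <- list(); posthoc <- list()
  for (m in metrics) {
    v <- profile[[m]]
    ok <- is.finite(v)
    gl <- split(v[ok], profile[[group]][ok])
    gl <- gl[lengths(gl) > 0]
    if (length(gl) < 2 || sum(lengths(gl)) < 3) next
    kw <- kruskal_wallis(gl)
    omnibus[[m]] <- data.frame(metric = m, H = kw$H, df = kw$df,
                               p_value = kw$p_value, method = kw$method,
                               stringsAsFactors = FALSE)
    if (kw$p_value < 0.05 || force_posthoc)
      posthoc[[m]] <- pairwise_wilcoxon(gl)
  }
  omni <- if (length(omnibus)) do.call(rbind, omnibus) else NULL
  if (!is.null(omni)) rownames(omni) <- NULL
  list(omnibus = omni, posthoc = posthoc)
}
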