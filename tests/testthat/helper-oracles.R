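# Independent oracles used across the suite. Everything here works from
# first principles (path enumeration, exhaustive subsets/permutations) and
# never calls the package functions it is used to check.

# root path of a tip: edge indices from the tip up to the root
.root_path_edges <- function(tree, tip_label) {
  tip <- match(tip_label, tree$tip.label)
  path <- integer(0)
  node <- tip
  repeat {
    k <- which(tree$edge[, 2] == node)
    if (length(k) == 0L) break
    path <- c(path, k)
    node <- tree$edge[k, 1]
  }
  path
}

# brute-force patristic distance between two tips: sum the branch lengths
# on the symmetric difference of the two root paths
bf_patristic <- function(tree, a, b) {
  pa <- .root_path_edges(tree, a)
  pb <- .root_path_edges(tree, b)
  shared <- intersect(pa, pb)
  sum(tree$edge.length[setdiff(pa, shared)]) +
    sum(tree$edge.length[setdiff(pb, shared)])
}

bf_patristic_matrix <- function(tree) {
  tips <- tree$tip.label
  m <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (i < j) m[i, j] <- m[j, i] <- bf_patristic(tree, tips[i], tips[j])
  }
  m
}

# brute-force MRCA-rooted spanning-subtree length: an edge belongs to the
# spanning subtree iff it lies on at least one tip's root path but not on
# all of them (edges on every path sit at or above the MRCA)
bf_subtree_length <- function(tree, tips) {
  if (length(tips) < 2) return(0)
  paths <- lapply(tips, function(t) .root_path_edges(tree, t))
  in_any <- Reduce(union, paths)
  in_all <- Reduce(intersect, paths)
  sum(tree$edge.length[setdiff(in_any, in_all)])
}

# exhaustive rarefaction: expected distinct species over all C(n, m)
# subsamples of the individual list
bf_rarefied_richness <- function(counts, m) {
  individuals <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(individuals), m)
  mean(apply(subs, 2, function(ix) length(unique(individuals[ix]))))
}

# exhaustive richness-constrained null: all C(|pool|, k) communities,
# scored with a caller-supplied metric function
bf_null_moments <- function(pool, k, metric_fun) {
  subs <- utils::combn(length(pool), k)
  vals <- apply(subs, 2, function(ix) metric_fun(pool[ix]))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

# mean pairwise distance straight off the matrix definition
bf_mpd <- function(d, sp) {
  pairs <- utils::combn(sp, 2)
  mean(apply(pairs, 2, function(p) d[p[1], p[2]]))
}

# small survey fixture builder
make_survey <- function(...) {
  as_survey_table(data.frame(..., stringsAsFactors = FALSE))
}

survey_row <- function(species, transect = "t1", habitat = "forest",
                       season = "spring", count = 1L, band = "B0_5",
                       zone = "outside") {
  data.frame(species_id = species, transect_id = transect,
             habitat = habitat, season = season, count = as.integer(count),
             height_band = band, zone = zone, stringsAsFactors = FALSE)
}

make_traits <- function(ids, mass, hwi, diet, stratum) {
  as_trait_table(data.frame(species_id = ids, body_mass = mass, hwi = hwi,
                            diet = diet, stratum = stratum,
                            stringsAsFactors = FALSE))
}
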