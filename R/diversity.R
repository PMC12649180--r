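#' Gower distance over the four functional traits
#'
#' Mixed-type dissimilarity on the trait table: for the continuous traits
#' the per-trait dissimilarity is \code{|x_i - x_j| / range}, with body
#' mass log-transformed first (mass spans orders of magnitude and is
#' analysed on the log scale throughout functional ecology; on the raw
#' scale the heaviest pair would dominate every comparison); the
#' hand-wing index is used as is. For the categorical traits (diet,
#' vertical stratum) the dissimilarity is a 0/1 mismatch indicator. The
#' Gower distance is the unweighted mean of the four, hence bounded in
#' [0, 1]. A continuous trait with zero observed range contributes 0 to
#' every pair and triggers a warning.
#'
#' @param traits a \code{trait_table} (see \code{\link{read_traits}}).
#' @return symmetric distance matrix with species ids as dimnames.
#' @export
gower_distance <- function(traits) {
  if (nrow(traits) < 2) abort("need at least 2 species")
  sp <- traits$species_id
  n <- length(sp)
  acc <- matrix(0, n, n, dimnames = list(sp, sp))
  for (col in c("body_mass", "hwi")) {
    v <- if (col == "body_mass") log(traits[[col]]) else traits[[col]]
    rng <- diff(range(v))
    if (rng == 0) {
      warning("trait '", col, "' has zero range; it contributes 0 to all pairs")
      next
    }
    acc <- acc + abs(outer(v, v, "-")) / rng
  }
  for (col in c("diet", "stratum")) {
    v <- traits[[col]]
    acc <- acc + (outer(v, v, "!=")) * 1
  }
  d <- acc / 4
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared-distance matrix, eigendecomposes it, and
#' returns coordinates on the axes with positive eigenvalues (at most
#' \code{k}), ordered by decreasing eigenvalue. For an exactly Euclidean
#' input matrix the embedding reproduces the input distances.
#'
#' @param d symmetric distance matrix.
#' @param k maximum number of axes to keep (default: all positive axes).
#' @return list with \code{points} (n x k' coordinate matrix),
#'   \code{eigenvalues} (all n, decreasing), \code{prop_explained}
#'   (fraction of the positive-eigenvalue sum captured by the kept axes).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 points")
  A <- -0.5 * d^2
  # double centring: B = (I - 11'/n) A (I - 11'/n)
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) == 0L) abort("degenerate distances: no positive eigenvalues")
  keep <- pos[seq_len(min(length(pos), k %||% length(pos)))]
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_along(keep))
  list(points = pts, eigenvalues = e$values,
       prop_explained = sum(e$values[keep]) / sum(e$values[pos]))
}

#' Euclidean distance matrix from a coordinate matrix
#' @param pts rows = points.
#' @return symmetric distance matrix.
#' @keywords internal
euclidean_distances <- function(pts) {
  as.matrix(stats::dist(pts))
}

#' UPGMA functional dendrogram
#'
#' Average-linkage agglomerative clustering of a distance matrix into a
#' rooted ultrametric tree, returned as an \code{ape} \code{phylo}. The
#' merge height is half the average inter-cluster distance, so cophenetic
#' (tip-to-tip) distances on the dendrogram equal the average-linkage
#' distances. Ties are broken deterministically: among equally close pairs
#' the pair whose (sorted) representative labels are lexicographically
#' smallest merges first, each cluster being represented by its smallest
#' member label.
#'
#' @param d symmetric distance matrix with unique labels.
#' @return ultrametric \code{phylo} with the input labels as tips.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 species")
  if (is.null(labs) || any(duplicated(labs))) abort("labels must be unique")

  D <- d
  node <- seq_len(n)          # phylo node id of each active cluster
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_lab <- labs
  merges <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(node)
    Dl <- D
    Dl[!upper.tri(Dl)] <- Inf
    dmin <- min(Dl)
    cand <- which(Dl == dmin, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      key2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      cand <- cand[order(key1, key2), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    h <- dmin / 2
    merges[[step]] <- list(children = node[c(i, j)],
                           child_heights = height[c(i, j)], height = h)
    # average-linkage update against every other cluster
    others <- setdiff(seq_len(m), c(i, j))
    newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
      (size[i] + size[j])
    keep <- others
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    node <- c(node[keep], n + step)
    size <- c(size[keep], size[i] + size[j])
    height <- c(height[keep], h)
    rep_lab <- c(rep_lab[keep], min(rep_lab[i], rep_lab[j]))
  }

  # internal ids were assigned in merge order n+1..2n-1; phylo wants the
  # root (last merge) to be n+1, so reverse the internal numbering
  remap <- function(id) ifelse(id <= n, id, n + (2L * n - id))
  edge <- matrix(0L, 2L * (n - 1L), 2)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (step in seq_len(n - 1L)) {
    mg <- merges[[step]]
    parent <- remap(n + step)
    for (c_i in 1:2) {
      r <- r + 1L
      edge[r, ] <- c(parent, remap(mg$children[c_i]))
      elen[r] <- mg$height - mg$child_heights[c_i]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen, tip.label = labs,
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# Per-edge tip membership of a tree: logical matrix (edges x tips), entry
# TRUE when the tip descends from the edge's child node. Shared by PD, FD
# and the vectorized null models.
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tree$Nnode
  below <- matrix(FALSE, nnode, n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  M <- below[tree$edge[, 2], , drop = FALSE]
  colnames(M) <- tree$tip.label
  M
}

#' Faith's phylogenetic diversity of a community
#'
#' Total branch length of the minimal subtree connecting the community's
#' species on the phylogeny, rooted at their most recent common ancestor
#' (the path from the MRCA up to the tree root is excluded). A
#' single-species community has PD = 0 by this convention.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param community character vector of tip labels.
#' @return PD value (sum of branch lengths).
#' @export
faith_pd <- function(tree, community) {
  community <- unique(as.character(community))
  missing <- setdiff(community, tree$tip.label)
  if (length(missing))
    abort("species absent from tree: ", paste(missing, collapse = ", "))
  if (length(community) < 2) return(0)
  M <- edge_tip_incidence(tree)
  subtree_length(M, tree$edge.length, tree$tip.label %in% community)
}

# spanning-subtree length from a precomputed incidence matrix; `present`
# is a logical vector over tips. Edges above the MRCA carry all n present
# tips and are excluded.
subtree_length <- function(M, edge_len, present) {
  n <- sum(present)
  if (n < 2) return(0)
  cnt <- as.vector(M %*% present)
  sum(edge_len[cnt >= 1 & cnt < n])
}

#' Petchey-Gaston functional diversity of a community
#'
#' Total branch length of the subtree of the functional dendrogram spanning
#' the community's species — the same spanning-subtree convention as
#' \code{\link{faith_pd}} (MRCA-rooted, root path excluded, singleton = 0).
#'
#' @param dendro ultrametric \code{phylo} from \code{\link{upgma}}.
#' @param community character vector of species ids.
#' @return FD value.
#' @export
dendrogram_fd <- function(dendro, community) {
  faith_pd(dendro, community)
}

#' Patristic distance matrix of a phylogeny
#'
#' Tip-to-tip path-length distances (sum of branch lengths along the unique
#' path joining two tips).
#'
#' @param tree a \code{phylo} with branch lengths.
#' @return symmetric distance matrix, tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' Mean pairwise distance of a community
#'
#' \deqn{MPD = \sum_{i \ne j} \delta(i,j) / (n (n-1))} over ordered pairs,
#' i.e. the mean of the off-diagonal entries of the community submatrix —
#' abundance-unweighted. Used both for functional (MFD) and phylogenetic
#' (MPD) structure depending on the distance matrix supplied. Undefined
#' for n < 2: returns NA with a warning.
#'
#' @param d distance matrix covering the community's species.
#' @param community character vector of species ids.
#' @return mean pairwise distance, or NA if n < 2.
#' @export
mean_pairwise_distance <- function(d, community) {
  community <- unique(as.character(community))
  missing <- setdiff(community, rownames(d))
  if (length(missing))
    abort("species absent from distance matrix: ",
          paste(missing, collapse = ", "))
  n <- length(community)
  if (n < 2) {
    warning("mean pairwise distance undefined for n < 2; returning NA")
    return(NA_real_)
  }
  sub <- d[community, community]
  sum(sub) / (n * (n - 1))
}

#' Functional and phylogenetic structures for a species pool
#'
#' Builds, once per analysis, everything the diversity and null-model
#' stages need: the Gower trait distance matrix, its PCoA embedding and
#' the Euclidean functional distance matrix in that space (used for MFD),
#' the UPGMA functional dendrogram (used for FD), the pruned phylogeny and
#' its patristic distance matrix (used for PD and MPD).
#'
#' @param traits \code{trait_table} covering the pool.
#' @param tree phylogeny covering the pool (extra tips are pruned away).
#' @param species character vector: the species pool. Defaults to the
#'   trait table's species.
#' @param fd_space \code{"gower"} (default) to build the dendrogram
#'   directly on the Gower matrix, or \code{"pcoa"} to build it on
#'   Euclidean distances in the PCoA space.
#' @param allow_drop if TRUE, pool species missing from traits or tree are
#'   dropped with a message instead of raising an error.
#' @return list with \code{species}, \code{gower}, \code{pcoa},
#'   \code{fdist}, \code{dendro}, \code{tree}, \code{pdist}.
#' @export
community_structures <- function(traits, tree, species = NULL,
                                 fd_space = c("gower", "pcoa"),
                                 allow_drop = FALSE) {
  fd_space <- match.arg(fd_space)
  species <- sort(unique(species %||% traits$species_id))
  miss <- union(setdiff(species, traits$species_id),
                setdiff(species, tree$tip.label))
  if (length(miss)) {
    if (!allow_drop)
      abort("species missing from traits or tree: ",
            paste(miss, collapse = ", "),
            " (set allow_drop = TRUE to drop them)")
    message("dropping ", length(miss), " species missing from traits/tree: ",
            paste(miss, collapse = ", "))
    species <- setdiff(species, miss)
  }
  if (length(species) < 3) abort("need at least 3 species in the pool")
  tr <- traits[match(species, traits$species_id), , drop = FALSE]
  g <- gower_distance(tr)
  pc <- pcoa(g)
  fdist <- euclidean_distances(pc$points)
  dendro <- upgma(if (fd_space == "gower") g else fdist)
  ptree <- if (length(setdiff(tree$tip.label, species)))
    prune_tree(tree, species) else tree
  list(species = species, gower = g, pcoa = pc, fdist = fdist,
       dendro = dendro, tree = ptree, pdist = patristic_distances(ptree),
       fd_space = fd_space)
}

#' Per-assemblage diversity profile
#'
#' Computes, for every column of a community matrix: species richness (SR),
#' abundance, functional diversity (FD: dendrogram subtree length),
#' phylogenetic diversity (PD: Faith's PD), mean pairwise functional
#' distance (MFD: Euclidean in PCoA trait space) and mean pairwise
#' phylogenetic distance (MPD: patristic). MFD/MPD are NA for assemblages
#' with fewer than 2 species.
#'
#' @param comm community matrix (species x assemblage).
#' @param structures result of \code{\link{community_structures}} covering
#'   the matrix's species.
#' @return data frame, one row per assemblage, with the assemblage metadata
#'   columns carried over.
#' @export
diversity_profile <- function(comm, structures) {
  sp <- rownames(comm)
  miss <- setdiff(sp, structures$species)
  if (length(miss))
    abort("community species missing from structures: ",
          paste(miss, collapse = ", "))
  Mf <- edge_tip_incidence(structures$dendro)
  Mp <- edge_tip_incidence(structures$tree)
  rows <- lapply(colnames(comm), function(a) {
    pres <- sp[comm[, a] > 0]
    n <- length(pres)
    data.frame(assemblage = a, SR = n, abundance = sum(comm[, a]),
      FD = subtree_length(Mf, structures$dendro$edge.length,
                          structures$dendro$tip.label %in% pres),
      PD = subtree_length(Mp, structures$tree$edge.length,
                          structures$tree$tip.label %in% pres),
      MFD = if (n >= 2) mean_pairwise_distance(structures$fdist, pres)
            else NA_real_,
      MPD = if (n >= 2) mean_pairwise_distance(structures$pdist, pres)
            else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meta <- attr(comm, "meta")
  if (!is.null(meta)) out <- merge(meta, out, by = "assemblage", sort = TRUE)
  out
}
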