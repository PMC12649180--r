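test_that("gower distance follows the four-trait recipe", {
  tr <- make_traits(c("a", "b", "c"),
                    mass = c(1, 10, 100), hwi = c(5, 5, 10),
                    diet = c("x", "x", "y"), stratum = c("g", "g", "g"))
  g <- gower_distance(tr)
  expect_equal(diag(g), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(g, t(g))
  # rows equal except log-mass at half its range: (0.5 + 0 + 0 + 0)/4
  expect_equal(g["a", "b"], 0.5 / 4)
  # a vs c: log-mass full range (1) + hwi full range (1) + diet mismatch (1)
  expect_equal(g["a", "c"], 3 / 4)
  # identical rows -> 0; maximal difference -> 1
  tr2 <- make_traits(c("p", "q"), mass = c(1, 100), hwi = c(2, 50),
                     diet = c("x", "y"), stratum = c("g", "c"))
  g2 <- gower_distance(tr2)
  expect_equal(g2["p", "q"], 1)
  tr3 <- make_traits(c("p", "q"), mass = c(3, 3), hwi = c(2, 9),
                     diet = "x", stratum = "g")
  expect_warning(g3 <- gower_distance(tr3), "zero range")
  expect_equal(g3["p", "q"], 1 / 4)  # only hwi differs; mass contributes 0
  expect_error(gower_distance(tr3[1, ]), "2 species")
})

test_that("gower distance agrees with cluster::daisy on mixed traits", {
  skip_if_not_installed("cluster")
  set.seed(31)
  tr <- make_traits(sprintf("s%02d", 1:12),
                    mass = rlnorm(12, 4, 1), hwi = runif(12, 10, 60),
                    diet = sample(letters[1:3], 12, TRUE),
                    stratum = sample(LETTERS[1:4], 12, TRUE))
  g <- gower_distance(tr)
  df <- data.frame(mass = log(tr$body_mass), hwi = tr$hwi,
                   diet = factor(tr$diet), stratum = factor(tr$stratum))
  d <- as.matrix(cluster::daisy(df, metric = "gower"))
  dimnames(d) <- dimnames(g)
  expect_equal(g, d, tolerance = 1e-10)
})

test_that("pcoa round-trips Euclidean distance matrices", {
  set.seed(13)
  pts <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("p", 1:5), NULL))
  d <- as.matrix(dist(pts))
  emb <- pcoa(d)
  expect_equal(as.matrix(dist(emb$points)), d, tolerance = 1e-8)
  expect_equal(emb$prop_explained, 1, tolerance = 1e-8)
  # two points at distance d -> coordinates +/- d/2 on one axis
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  emb2 <- pcoa(d2)
  expect_equal(sort(as.numeric(emb2$points[, 1])), c(-1.5, 1.5))
  # collinear points -> a single positive axis
  line <- as.matrix(dist(cbind(c(0, 1, 3, 6))))
  dimnames(line) <- list(paste0("q", 1:4), paste0("q", 1:4))
  embl <- pcoa(line)
  expect_equal(ncol(embl$points), 1L)
  expect_equal(as.matrix(dist(embl$points)), line, tolerance = 1e-8)
  # agreement with classical scaling in stats
  cmd <- stats::cmdscale(d, k = 4)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(cmd)),
               tolerance = 1e-8)
})

test_that("upgma reproduces hand-computed merges and is ultrametric", {
  # d(A,B)=2, d(A,C)=d(B,C)=6: AB at height 1, then C at height 3
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_s3_class(tr, "phylo")
  coph <- stats::cophenetic(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  # total branch length: tips A,B at 1 + 1, C at 3, AB node to root 2
  expect_equal(sum(tr$edge.length), 1 + 1 + 3 + 2)
  # 2 species at distance d: single merge at height d/2
  d2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- upgma(d2)
  expect_equal(sum(tr2$edge.length), 5)
  # deterministic tie-breaking: equal distances, identical across runs
  de <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  expect_identical(ape::write.tree(upgma(de)), ape::write.tree(upgma(de)))
})

test_that("upgma cophenetic distances match hclust average linkage", {
  set.seed(17)
  pts <- matrix(rnorm(24), 8)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  tr <- upgma(d)
  hc <- stats::hclust(as.dist(d), method = "average")
  # hclust heights are average distances; cophenetic on the phylo is the
  # same quantity because merge height = distance / 2 on each side
  expect_equal(stats::cophenetic(tr)[paste0("s", 1:8), paste0("s", 1:8)],
               as.matrix(stats::cophenetic(hc))[paste0("s", 1:8),
                                                paste0("s", 1:8)],
               tolerance = 1e-10)
})

test_that("faith_pd and dendrogram_fd equal brute-force path sums", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  expect_equal(faith_pd(tree, c("A", "B", "C")), 5)  # all branches
  expect_equal(faith_pd(tree, c("A", "C")), 4)   # 1 + 1 + 2
  expect_equal(faith_pd(tree, c("A", "B")), 2)
  expect_equal(faith_pd(tree, "A"), 0)           # singleton convention
  expect_error(faith_pd(tree, c("A", "Z")), "absent")
  # oracle sweep on random trees and random communities (<= 10 tips)
  for (rep in 1:6) {
    tr <- simulate_tree(sim_config(n_species = 10, seed = 100 + rep))
    for (k in c(2, 4, 7, 10)) {
      set.seed(rep * 10 + k)
      comm <- sample(tr$tip.label, k)
      expect_equal(faith_pd(tr, comm), bf_subtree_length(tr, comm),
                   tolerance = 1e-12)
    }
    # full community = total branch length below the root
    expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length),
                 tolerance = 1e-12)
  }
  # FD on a dendrogram: same spanning-subtree machinery
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(d)
  expect_equal(dendrogram_fd(dend, c("A", "B")),
               bf_subtree_length(dend, c("A", "B")))
  expect_equal(dendrogram_fd(dend, c("A", "C")),
               bf_subtree_length(dend, c("A", "C")))
})

test_that("faith_pd agrees with picante on a random tree", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(sim_config(n_species = 12, seed = 5))
  set.seed(6)
  comm <- sample(tr$tip.label, 6)
  samp <- matrix(as.integer(tr$tip.label %in% comm), 1,
                 dimnames = list("c1", tr$tip.label))
  pic <- picante::pd(samp, tr, include.root = FALSE)$PD
  expect_equal(faith_pd(tr, comm), pic, tolerance = 1e-10)
})

test_that("FD and PD are monotone under adding species", {
  tr <- simulate_tree(sim_config(n_species = 9, seed = 21))
  set.seed(22)
  comm <- sample(tr$tip.label, 3)
  rest <- setdiff(tr$tip.label, comm)
  pd0 <- faith_pd(tr, comm)
  for (s in rest) {
    pd1 <- faith_pd(tr, c(comm, s))
    expect_gte(pd1, pd0 - 1e-12)
  }
})

test_that("mean pairwise distance matches the ordered-pair formula", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(mean_pairwise_distance(d, c("A", "B", "C")), 2)
  expect_equal(mean_pairwise_distance(d, c("A", "B")), 1)  # collapses
  expect_warning(v <- mean_pairwise_distance(d, "A"), "n < 2")
  expect_true(is.na(v))
  # invariance to ordering
  expect_equal(mean_pairwise_distance(d, c("C", "A", "B")),
               mean_pairwise_distance(d, c("A", "B", "C")))
  # clones -> 0
  dz <- matrix(0, 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  expect_equal(mean_pairwise_distance(dz, c("u", "v")), 0)
  # random check against combn oracle
  set.seed(41)
  tr <- simulate_tree(sim_config(n_species = 8, seed = 42))
  pd <- patristic_distances(tr)
  comm <- sample(tr$tip.label, 5)
  expect_equal(mean_pairwise_distance(pd, comm), bf_mpd(pd, comm),
               tolerance = 1e-12)
})

test_that("diversity profile assembles all metrics per assemblage", {
  cfg <- sim_config(n_species = 25,
                    n_transects = c(forest = 2, wetland = 2), seed = 77)
  ds <- simulate_dataset(cfg)
  comm <- build_community_matrix(ds$survey, "habitat")
  st <- community_structures(ds$traits, ds$tree, rownames(comm))
  prof <- diversity_profile(comm, st)
  expect_equal(nrow(prof), ncol(comm))
  expect_equal(prof$SR, unname(colSums(comm > 0)))
  expect_equal(prof$abundance, unname(colSums(comm)))
  for (i in seq_len(nrow(prof))) {
    pres <- rownames(comm)[comm[, prof$assemblage[i]] > 0]
    expect_equal(prof$PD[i], faith_pd(st$tree, pres))
    expect_equal(prof$FD[i], dendrogram_fd(st$dendro, pres))
    if (length(pres) >= 2) {
      expect_equal(prof$MPD[i], mean_pairwise_distance(st$pdist, pres))
      expect_equal(prof$MFD[i], mean_pairwise_distance(st$fdist, pres))
    }
  }
})
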