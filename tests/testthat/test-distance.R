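test_that("gower handles identical, maximal and random cases", {
  sch <- default_trait_schema()
  # identical trait rows -> d = 0
  tr <- random_traits(3, seed = 5)
  tr[2, sch$trait] <- tr[1, sch$trait]
  d <- suppressMessages(gower_dissimilarity(tr, sch))
  expect_equal(unname(d[1, 2]), 0)

  # masses at the pool extremes with all 25 binary traits opposite -> d = 1
  bin <- sch$trait[sch$type == "binary"]
  tr2 <- random_traits(2, seed = 6)
  tr2$body_mass <- c(2, 2172)
  tr2[1, bin] <- as.list(rep(0, 25))
  tr2[2, bin] <- as.list(rep(1, 25))
  d2 <- gower_dissimilarity(tr2, sch)
  expect_equal(unname(d2[1, 2]), 1)

  # random 4-species table matches the per-trait arithmetic oracle
  tr4 <- random_traits(4, seed = 7)
  expect_equal(unclass(gower_dissimilarity(tr4, sch))[, ],
               gower_oracle(tr4, sch), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("gower agrees with an independent mixed-trait implementation", {
  # cluster::daisy with standard Gower scaling is the independent oracle
  sch <- default_trait_schema()
  tr <- random_traits(12, seed = 8)
  d <- gower_dissimilarity(tr, sch)
  df <- as.data.frame(tr[sch$trait])
  ref <- as.matrix(suppressWarnings(cluster::daisy(df, metric = "gower")))
  expect_equal(unclass(d)[, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gower is invariant to trait and species order, and in [0, 1]", {
  sch <- default_trait_schema()
  tr <- random_traits(10, seed = 11)
  d <- gower_dissimilarity(tr, sch)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 10))
  expect_equal(unclass(d), unclass(t(d)), ignore_attr = TRUE)

  set.seed(3)
  sch_perm <- sch[sample(nrow(sch)), ]
  d_perm <- gower_dissimilarity(tr, sch_perm)
  expect_equal(unclass(d)[, ], unclass(d_perm)[, ], tolerance = 1e-12)

  rows <- sample(nrow(tr))
  d_rows <- gower_dissimilarity(tr[rows, ], sch)
  expect_equal(unclass(d_rows)[tr$species_id, tr$species_id],
               unclass(d)[tr$species_id, tr$species_id], tolerance = 1e-12)
})

test_that("binary-only gower equals the simple matching distance", {
  sch_bin <- trait_schema(
    trait = c("a", "b", "c", "d"),
    type = "binary", category = "food_type"
  )
  tr <- tibble::tibble(
    species_id = c("x", "y", "z"),
    a = c(1, 0, 1), b = c(0, 1, 0), c = c(1, 1, 0), d = c(0, 0, 1)
  )
  d <- suppressMessages(gower_dissimilarity(tr, sch_bin))
  mism <- function(i, j) sum(tr[i, c("a", "b", "c", "d")] != tr[j, c("a", "b", "c", "d")]) / 4
  expect_equal(unname(d["x", "y"]), mism(1, 2))
  expect_equal(unname(d["x", "z"]), mism(1, 3))
  expect_equal(unname(d["y", "z"]), mism(2, 3))
})

test_that("gower errors on zero continuous range and supports pool ranging", {
  sch <- mini_schema()
  tr <- mini_traits()
  tr$body_mass <- 50
  expect_error(gower_dissimilarity(tr, sch), "zero range")

  # subset distances with pool ranges equal the pool submatrix
  tr <- random_traits(8, seed = 12)
  sch26 <- default_trait_schema()
  d_pool <- gower_dissimilarity(tr, sch26)
  sub <- tr[c(2, 5, 7), ]
  d_sub <- gower_dissimilarity(sub, sch26, ranges = attr(d_pool, "ranges"))
  expect_equal(unclass(d_sub)[, ],
               unclass(d_pool)[sub$species_id, sub$species_id],
               tolerance = 1e-12)
})

test_that("cailliez-corrected principal coordinates reproduce distances", {
  # already-Euclidean input: 3 collinear points, c = 0
  x <- c(0, 1, 3)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(letters[1:3], letters[1:3])
  sp <- pcoa_cailliez(d)
  expect_equal(sp$correction, 0)
  expect_equal(as.matrix(stats::dist(sp$coordinates)), d,
               tolerance = 1e-8, ignore_attr = TRUE)

  # non-Euclidean 4-point counterexample: corrected distances = d + c
  dne <- matrix(c(0, 1, 1, 1,
                  1, 0, 2, 2,
                  1, 2, 0, 2,
                  1, 2, 2, 0), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  spn <- pcoa_cailliez(dne)
  expect_gt(spn$correction, 0)
  expected <- dne + spn$correction
  diag(expected) <- 0
  expect_equal(as.matrix(stats::dist(spn$coordinates)), expected,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(spn$eigenvalues >= -1e-8))

  # against the reference correction in ape on a realistic Gower matrix
  tr <- random_traits(15, seed = 13)
  dg <- gower_dissimilarity(tr, default_trait_schema())
  ours <- pcoa_cailliez(dg)
  ref <- ape::pcoa(stats::as.dist(unclass(dg)), correction = "cailliez")
  ref_coords <- if (!is.null(ref$vectors.cor)) ref$vectors.cor else ref$vectors
  expect_equal(as.matrix(stats::dist(ours$coordinates)),
               as.matrix(stats::dist(ref_coords)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("upgma merges as hand-computed and is ultrametric", {
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- upgma_dendrogram(d2)
  expect_equal(hc2$height, 0.6)

  d3 <- matrix(c(0, 0.2, 0.8,
                 0.2, 0, 0.8,
                 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- upgma_dendrogram(d3)
  expect_equal(hc3$height, c(0.2, 0.8))  # {A,B} at 0.2, then C at 0.8

  # heights non-decreasing and cophenetic ultrametric on random input
  tr <- random_traits(12, seed = 14)
  hc <- upgma_dendrogram(gower_dissimilarity(tr, default_trait_schema()))
  expect_true(all(diff(hc$height) >= -1e-12))
  cop <- as.matrix(stats::cophenetic(hc))
  n <- nrow(cop)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- sort(c(cop[i, j], cop[i, k], cop[j, k]))
    expect_lte(trio[3], trio[2] + 1e-12)  # two largest equal
  }
})

test_that("dendrogram exports to newick with branch lengths", {
  d3 <- matrix(c(0, 0.2, 0.8,
                 0.2, 0, 0.8,
                 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_dendrogram(d3)
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # leaf-to-leaf path lengths reproduce the cophenetic distances
  cop <- as.matrix(stats::cophenetic(hc))
  pat <- ape::cophenetic.phylo(phy)
  expect_equal(pat[rownames(cop), colnames(cop)], cop, tolerance = 1e-8)
})

test_that("mst picks minimal edges, matching brute-force enumeration", {
  # 3 collinear equally spaced points: the two short edges
  coords <- matrix(c(0, 1, 2, 0, 0, 0), ncol = 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  e <- mst_edges(coords)
  expect_equal(nrow(e), 2)
  expect_equal(sum(e$length), 2)

  # 5 random points: total length equals the spanning-tree minimum
  set.seed(21)
  for (rep in 1:3) {
    pts <- matrix(stats::runif(10), 5, 2)
    rownames(pts) <- letters[1:5]
    e5 <- mst_edges(pts)
    expect_equal(nrow(e5), 4)
    expect_equal(sum(e5$length), mst_bruteforce(pts), tolerance = 1e-10)
  }

  # duplicated point: zero-length edge, still n - 1 edges
  dup <- matrix(c(0, 0, 1, 0, 0, 0), ncol = 2,
                dimnames = list(c("a", "b", "c"), NULL))
  ed <- mst_edges(dup)
  expect_equal(nrow(ed), 2)
  expect_true(any(ed$length == 0))
})

test_that("branch_length_sum matches the reference tree-height routine", {
  for (s in c(19, 20, 21)) {
    tr <- random_traits(10, seed = s)
    hc <- upgma_dendrogram(gower_dissimilarity(tr, default_trait_schema()))
    expect_equal(branch_length_sum(hc), vegan::treeheight(hc),
                 tolerance = 1e-10)
  }
})
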