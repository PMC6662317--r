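pool_fixture <- function(n = 10, seed = 31) {
  tr <- random_traits(n, seed = seed)
  d <- suppressMessages(gower_dissimilarity(tr, default_trait_schema()))
  list(traits = tr, d = d, space = pcoa_cailliez(d))
}

test_that("FD equals the hand-built dendrogram edge sum", {
  fx <- pool_fixture()
  expect_equal(fd_index(fx$d, fx$traits$species_id[1]), 0)  # S = 1

  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(fd_index(d2, c("a", "b")), 1.2)  # two 0.6 leaf segments

  # 3-species hand case: merges at 0.2 and 0.8
  # edges: two leaf segments of 0.2, the {A,B}-node segment 0.8 - 0.2 = 0.6,
  # and C's leaf segment 0.8 -> total 1.8
  d3 <- matrix(c(0, 0.2, 0.8,
                 0.2, 0, 0.8,
                 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(fd_index(d3, c("A", "B", "C")), 1.8)
  expect_equal(fd_index(d3, c("A", "B", "C")),
               vegan::treeheight(upgma_dendrogram(d3)))

  expect_error(fd_index(d3, c("A", "nope")), "absent")
})

test_that("FEve is 1 for perfectly even communities and NA below S = 3", {
  coords <- matrix(c(0, 1, 2, 0, 0, 0), ncol = 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  p <- c(a = 1/3, b = 1/3, c = 1/3)
  expect_equal(feve_index(coords, p), 1)
  expect_true(is.na(suppressMessages(feve_index(coords[1:2, ], p[1:2] * 1.5))))
})

test_that("FEve matches the step-by-step EW/PEW oracle on 4-point cases", {
  set.seed(41)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(8), 4, 2)
    rownames(pts) <- letters[1:4]
    p <- stats::runif(4); p <- p / sum(p); names(p) <- letters[1:4]
    expect_equal(feve_index(pts, p), feve_oracle(pts, unname(p)),
                 tolerance = 1e-10)
  }
})

test_that("FEve is invariant under rotation and translation of trait space", {
  set.seed(42)
  pts <- matrix(stats::runif(12), 6, 2)
  rownames(pts) <- letters[1:6]
  p <- stats::runif(6); p <- p / sum(p); names(p) <- letters[1:6]
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts2 <- sweep(pts %*% rot, 2, c(3, -7), "+")
  rownames(pts2) <- rownames(pts)
  expect_equal(feve_index(pts, p), feve_index(pts2, p), tolerance = 1e-10)
})

test_that("Rao equals the naive double sum and its identities hold", {
  expect_equal(rao_index(matrix(0, 1, 1, dimnames = list("a", "a")),
                         c(a = 1)), 0)
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(rao_index(d2, c(a = 0.5, b = 0.5)), 0.5)

  fx <- pool_fixture(6, seed = 43)
  set.seed(44)
  p <- stats::runif(6); p <- p / sum(p); names(p) <- fx$traits$species_id
  naive <- 0
  for (i in 1:6) for (j in 1:6) {
    naive <- naive + fx$d[names(p)[i], names(p)[j]] * p[i] * p[j]
  }
  expect_equal(rao_index(fx$d, p), unname(naive), tolerance = 1e-12)
  expect_lte(rao_index(fx$d, p), max(fx$d))

  # with d = 1 off-diagonal, Rao reduces to the uncorrected Simpson value
  ones <- matrix(1, 6, 6, dimnames = dimnames(unclass(fx$d)))
  diag(ones) <- 0
  expect_equal(rao_index(ones, p), 1 - sum(p^2), tolerance = 1e-12)
})

test_that("Jost correction and Simpson equivalents follow the closed forms", {
  expect_equal(jost_correct(0), 1)
  expect_equal(jost_correct(0.5), 2)
  expect_error(jost_correct(1), "\\[0, 1\\)")
  expect_error(jost_correct(-0.1), "\\[0, 1\\)")

  expect_equal(simpson_equivalent(1), 1)
  expect_equal(simpson_equivalent(c(0.5, 0.5)), 2)
  set.seed(45)
  p <- stats::runif(8); p <- p / sum(p)
  expect_equal(simpson_equivalent(p), 1 / sum(p^2), tolerance = 1e-12)
  # uniform p over S fully distinct species: D_eq = S
  expect_equal(simpson_equivalent(rep(1 / 7, 7)), 7, tolerance = 1e-12)
})

test_that("equivalent numbers ignore labels and zero-abundance padding", {
  fx <- pool_fixture(5, seed = 46)
  set.seed(47)
  p <- stats::runif(5); p <- p / sum(p); names(p) <- fx$traits$species_id
  q1 <- jost_correct(rao_index(fx$d, p))
  perm <- sample(5)
  expect_equal(jost_correct(rao_index(fx$d, p[perm])), q1, tolerance = 1e-12)
  expect_equal(simpson_equivalent(c(p, 0, 0)), simpson_equivalent(p),
               tolerance = 1e-12)
})

test_that("community_indices profiles sites across subgroups", {
  sch <- mini_schema()
  tr <- validate_trait_table(mini_traits(), sch)
  comm <- validate_community(mini_community(), tr)
  out <- suppressMessages(
    community_indices(comm, tr, sch, subgroups = c("ALL", "FGr"))
  )
  expect_setequal(unique(out$subgroup), c("ALL", "FGr"))
  all1 <- out[out$subgroup == "ALL" & out$site_id == "s1", ]
  expect_equal(all1$S, 3)  # spA, spB, spD present
  expect_equal(all1$D_eq, simpson_equivalent(c(3, 2, 1) / 6), tolerance = 1e-12)
  d <- gower_dissimilarity(tr, sch)
  expect_equal(all1$FD, fd_index(d, c("spA", "spB", "spD")), tolerance = 1e-12)
  expect_equal(all1$Q_eq, jost_correct(all1$Q), tolerance = 1e-12)
  # FGr = {spB, spC}: s1 holds only spB -> S = 1, FD = 0, FEve NA
  fgr1 <- out[out$subgroup == "FGr" & out$site_id == "s1", ]
  expect_equal(fgr1$S, 1)
  expect_equal(fgr1$FD, 0)
  expect_true(is.na(fgr1$FEve))
})
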