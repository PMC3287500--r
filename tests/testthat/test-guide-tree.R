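test_that("scores convert to distances monotonically with zero self-distance", {
  S <- matrix(c(10, 8, 2, 8, 10, 5, 2, 5, 10), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  D <- distances_from_scores(S)
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  expect_identical(D["a", "c"] > D["a", "b"], TRUE)  # lower score, larger distance
  set.seed(2)
  S2 <- matrix(sample(0:20, 25, replace = TRUE), 5, 5)
  S2[lower.tri(S2)] <- t(S2)[lower.tri(S2)]
  D2 <- distances_from_scores(S2)
  o <- upper.tri(S2)
  expect_equal(rank(-S2[o]), rank(D2[o]))
})

test_that("two nodes join directly with half the distance on each branch", {
  D <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_build(D)
  expect_identical(nrow(tr$merges), 1L)
  expect_identical(tr$merges$d_left, 3)
  expect_identical(tr$merges$d_right, 3)
  expect_error(nj_build(D[1, 1, drop = FALSE]), "at least 2")
})

test_that("neighbor joining recovers the generating topology from additive distances", {
  skip_if_not_installed("ape")
  # the classic 4-taxon additive example: ((a,b),(c,d)) with known branch lengths
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_build(D)
  expect_identical(nrow(tr$merges), 3L)                 # m - 1 merges
  first <- sort(unname(unlist(tr$merges[1, c("left", "right")])))
  expect_identical(first, c(1L, 2L))                    # a and b join first
  ph <- to_phylo(tr)
  ref <- ape::nj(stats::as.dist(D))
  expect_identical(ape::dist.topo(ape::unroot(ph), ape::unroot(ref))[[1]], 0)
  set.seed(31)
  for (r in 1:15) {
    m <- sample(5:7, 1)
    gen <- ape::rtree(m)                                # random generating tree
    D5 <- ape::cophenetic.phylo(gen)                    # its additive distances
    D5 <- D5[sort(rownames(D5)), sort(rownames(D5))]
    tr5 <- nj_build(D5)
    expect_identical(nrow(tr5$merges), m - 1L)
    expect_identical(length(unique(c(tr5$merges$left, tr5$merges$right,
                                     tr5$merges$node))), 2L * m - 1L)
    ph5 <- to_phylo(tr5)
    expect_identical(ape::dist.topo(ape::unroot(ph5),
                                    ape::unroot(ape::nj(stats::as.dist(D5))))[[1]], 0)
    expect_identical(ape::dist.topo(ape::unroot(ph5), ape::unroot(gen))[[1]], 0)
  }
})

test_that("relabelling the taxa permutes the tree identically", {
  skip_if_not_installed("ape")
  set.seed(13)
  D <- as.matrix(stats::dist(matrix(stats::runif(10), 5, 2)))
  rownames(D) <- colnames(D) <- paste0("s", 1:5)
  perm <- sample(5)
  Dp <- D[perm, perm]
  t1 <- to_phylo(nj_build(D))
  t2 <- to_phylo(nj_build(Dp))
  expect_identical(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[[1]], 0)
})

test_that("the literal distance-update variant runs and still yields m - 1 merges", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_build(D, literal_update = TRUE)
  expect_identical(nrow(tr$merges), 3L)
})

test_that("Newick output round-trips through an independent parser", {
  skip_if_not_installed("ape")
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_build(D)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, letters[1:4])
  expect_identical(ape::dist.topo(ape::unroot(back), ape::unroot(to_phylo(tr)))[[1]], 0)
})
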