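test_that("group alignment of singleton groups reduces to pairwise DP", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)  # already non-negative
  set.seed(61)
  for (r in 1:15) {
    x <- random_seq(sample(2:8, 1)); y <- random_seq(sample(2:8, 1))
    merged <- group_align(aligned_group(c(a = x)), aligned_group(c(b = y)), sc)
    aln <- rmesh_align(x, y, sc, "nw", engine = "reference")
    s <- group_strings(merged)
    expect_identical(unname(s["a"]), aln$x_aln)
    expect_identical(unname(s["b"]), aln$y_aln)
    expect_equal(attr(merged, "score"), unname(aln$score))
  }
})

test_that("aligning a group with itself adds no gaps", {
  g <- aligned_group(c(s1 = "AC-GT", s2 = "ACTGT"))
  m <- group_align(g, g, scoring_scheme(match = 2, mismatch = 0, gap = -1))
  expect_identical(ncol(m$mat), 5L)
  expect_identical(group_strings(m)[["s1"]], "AC-GT")
})

test_that("the group DP optimum equals exhaustive monotone-path enumeration", {
  sc <- scoring_scheme(match = 2, mismatch = -1, gap = -2)
  sc <- rmeshalign:::scheme_scale(sc)
  set.seed(88)
  for (r in 1:10) {
    raw <- stats::setNames(replicate(2, random_seq(sample(3:6, 1))), c("a1", "a2"))
    la <- max(nchar(raw))  # pad to equal length with trailing gaps
    A <- aligned_group(vapply(raw, function(s)
      paste0(s, strrep("-", la - nchar(s))), character(1)))
    B <- aligned_group(stats::setNames(
      rep(random_seq(sample(3:6, 1)), 2), c("b1", "b2")))
    scg <- rmeshalign:::.group_dp_scores(A, B, sc)
    C <- rmeshalign:::.group_dp_run(scg, "reference")
    expect_equal(C[scg$nA + 1L, scg$nB + 1L],
                 enum_group_paths(scg$d, scg$gA, scg$gB))
    # and the mesh engine computes the same optimum
    Cm <- rmeshalign:::.group_dp_run(scg, "mesh")
    expect_equal(unname(Cm), unname(C))
  }
})

test_that("a two-sequence MSA is the pairwise alignment", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  res <- progressive_msa(c(a = "GATTACA", b = "GCATGCA"), sc)
  aln <- rmesh_align("GATTACA", "GCATGCA", sc, "nw", engine = "reference")
  expect_identical(unname(res$alignment), c(aln$x_aln, aln$y_aln))
})

test_that("an identical pair merges first in the guide tree", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  res <- progressive_msa(c(a = "ACGTACGT", b = "TTTTGGCC", c = "ACGTACGT"), sc)
  first <- sort(unname(unlist(res$tree$merges[1, c("left", "right")])))
  expect_identical(first, c(1L, 3L))  # the two identical sequences
})

test_that("progressive MSA conserves the input residues and matches the sequential reference", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  set.seed(19)
  for (r in 1:6) {
    fam <- synth_family(m = sample(3:6, 1), n = sample(6:12, 1),
                        mutation = 0.15, indel = 0.08, seed = 1000 + r)
    res <- progressive_msa(fam$seqs, sc)
    expect_identical(length(unique(nchar(res$alignment))), 1L)     # rectangular
    expect_identical(unname(degap(res$alignment)), unname(fam$seqs))
    expect_identical(names(res$alignment), names(fam$seqs))        # input row order
    expect_identical(unname(res$alignment),
                     unname(oracle_progressive(fam$seqs, sc)))
  }
})

test_that("the mesh engine reproduces the reference pipeline end to end", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  fam <- synth_family(m = 5, n = 10, mutation = 0.15, indel = 0.05, seed = 424)
  mesh <- progressive_msa(fam$seqs, sc, engine = "mesh")
  ref <- progressive_msa(fam$seqs, sc, engine = "reference")
  expect_identical(mesh$alignment, ref$alignment)
  expect_identical(mesh$scores, ref$scores)
  expect_identical(mesh$merge_scores, ref$merge_scores)
})

test_that("per-merge scores are reproducible from the merged group's column pairs", {
  sc <- scoring_scheme(match = 2, mismatch = -1, gap = -1)
  fam <- synth_family(m = 4, n = 10, seed = 77)
  res <- progressive_msa(fam$seqs, sc)
  sc_used <- res$scheme
  # replay the final merge and rescore its columns by brute-force SP
  mg <- res$tree$merges
  final <- mg[nrow(mg), ]
  rebuild <- function(node) {
    if (node <= res$tree$m) return(aligned_group(fam$seqs[node]))
    row <- mg[mg$node == node, ]
    group_align(rebuild(row$left), rebuild(row$right), sc_used)
  }
  A <- rebuild(final$left); B <- rebuild(final$right)
  merged <- group_align(A, B, sc_used)
  nA <- nrow(A$mat)
  direct <- 0; diag_cols <- 0; i <- 0; j <- 0
  for (cc in seq_len(ncol(merged$mat))) {
    fa <- merged$mat[seq_len(nA), cc]
    fb <- merged$mat[-seq_len(nA), cc]
    isdiag <- any(fa != "-") && any(fb != "-")
    if (isdiag) { i <- i + 1; j <- j + 1 }
    else if (any(fa != "-")) i <- i + 1 else j <- j + 1
    if (i == 0 || j == 0) next  # leading gap run: free under the zero boundary
    direct <- direct + oracle_sp(fa, fb, sc_used$matrix)
    if (isdiag) diag_cols <- diag_cols + 1
  }
  expect_equal(attr(merged, "score"),
               direct + attr(merged, "beta_d") * diag_cols)
  expect_equal(attr(merged, "score"), res$merge_scores[nrow(mg)])
})

test_that("the resource log reproduces the closed-form unit accounting", {
  sc <- scoring_scheme(match = 1, mismatch = 0, gap = -1)    # unit-constant scheme
  fam <- synth_family(m = 4, n = 8, seed = 3)
  res <- progressive_msa(fam$seqs, sc)
  log <- res$resource_log
  n <- max(nchar(fam$seqs)); m <- length(fam$seqs)
  expect_identical(log$n, n)
  expect_identical(log$scheme_kind, "const")
  expect_identical(log$dp_cell, 10 * n)
  expect_identical(log$dp_per_mesh, 10 * n^3)
  expect_identical(log$nj, m^3)
  expect_identical(log$sp, m * n^2)
  expect_identical(log$total, m * 10 * n^3 + m^3 + m * n^2)
})
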