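test_that("the DP assembly wires the recurrence constants as in the cell diagram", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  a <- build_dp_mesh("AC", "AG", sc, "nw")
  expect_identical(a$sd, matrix(c(2, 0, 0, 0), 2, 2))  # diagonal "+" per symbol pair
  expect_identical(a$p, 1)                             # "-" units subtract |g|
  expect_error(build_dp_mesh("AC", "AG", scoring_scheme(match = 1, mismatch = -1), "nw"),
               "scaled")
  empty <- build_dp_mesh("AC", "", sc, "nw")           # degenerates to the first column
  expect_identical(run_dp(empty)$C, matrix(0L, 3, 1, dimnames = list(0:2, 0)))
})

test_that("self-alignment scores the full diagonal", {
  sc <- scoring_scheme(match = 3, mismatch = 0, gap = -1)
  m <- run_dp(build_dp_mesh("ACGT", "ACGT", sc, "nw"))
  expect_identical(m$C[5, 5], 12L)
})

test_that("mesh DP equals the sequential recurrence on random instances (all modes)", {
  set.seed(404)
  for (r in 1:25) {
    x <- random_seq(sample(0:10, 1)); y <- random_seq(sample(0:10, 1))
    sc <- random_scaled_scheme()
    for (mode in c("nw", "sw", "lcs")) {
      mesh <- run_dp(build_dp_mesh(x, y, sc, mode))
      want <- oracle_dp(x, y, sc, mode)$matrix
      expect_equal(unname(mesh$C), unname(want), ignore_attr = TRUE)
    }
  }
})

test_that("the LCS mesh agrees with brute-force subsequence enumeration", {
  set.seed(77)
  for (r in 1:25) {
    x <- random_seq(sample(1:8, 1), c("0", "1"))
    y <- random_seq(sample(1:8, 1), c("0", "1"))
    m <- run_dp(build_dp_mesh(x, y, scoring_scheme(), "lcs"))
    expect_identical(m$C[nchar(x) + 1L, nchar(y) + 1L],
                     as.integer(rmeshalign:::brute_force_lcs(x, y)))
  }
})

test_that("the LCS cell routes per the 4-way switch configuration", {
  expect_identical(lcs_cell_config(TRUE)$partition, "N|E|SW")
  expect_identical(lcs_cell_config(FALSE)$partition, "NS|E|W")
  expect_identical(lcs_cell_config(TRUE)$gap, 0L)
  w <- 8L
  cell <- function(dg, up, lf, match)
    un_decode(rmeshalign:::.lcs_cell_mesh(un_encode(dg, w), un_encode(up, w),
                                          un_encode(lf, w), match, w))
  expect_identical(cell(2, 0, 0, TRUE), 3L)   # match: diagonal + 1 passes
  expect_identical(cell(5, 3, 4, FALSE), 4L)  # mismatch: max(up, left), diagonal blocked
})

test_that("the staged max-location procedure matches a linear scan with the same tie rule", {
  M <- matrix(0, 5, 6); M[3, 4] <- 9
  expect_identical(find_max_location(M), c(i = 2L, j = 3L))
  expect_identical(find_max_location(matrix(1, 4, 4)), c(i = 0L, j = 0L))
  set.seed(55)
  for (r in 1:200) {
    nr <- sample(1:12, 1); nc <- sample(1:12, 1)
    C <- matrix(sample(0:6, nr * nc, replace = TRUE), nr, nc)
    expect_identical(find_max_location(C), oracle_argmax(C))
  }
})

test_that("traceback follows the winning ports and decodes a score-consistent alignment", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  ident <- dp_traceback(run_dp(build_dp_mesh("ACGT", "ACGT", sc, "nw")))
  expect_identical(ident$x_aln, "ACGT")
  expect_identical(ident$y_aln, "ACGT")
  gap <- dp_traceback(run_dp(build_dp_mesh("A", "", sc, "nw")))
  expect_identical(gap$x_aln, "A")
  expect_identical(gap$y_aln, "-")
  set.seed(909)
  for (r in 1:60) {
    x <- random_seq(sample(1:9, 1)); y <- random_seq(sample(1:9, 1))
    sc <- random_scaled_scheme()
    mode <- sample(c("nw", "sw"), 1)
    m <- run_dp(build_dp_mesh(x, y, sc, mode))
    aln <- dp_traceback(m)
    # the decoded path reproduces the matrix score from its start cell
    start_val <- m$C[aln$start[1L] + 1L, aln$start[2L] + 1L]
    expect_equal(start_val + path_score(m, aln), unname(aln$score))
    # and the end score is the oracle optimum for this scheme and mode
    expect_equal(unname(aln$score), oracle_dp(x, y, sc, mode)$score)
    # de-gapping the global alignment recovers both inputs
    if (mode == "nw") {
      expect_identical(degap(aln$x_aln), x)
      expect_identical(degap(aln$y_aln), y)
    }
  }
})

test_that("random ties admit a seeded random port choice", {
  sc <- scoring_scheme(match = 1, mismatch = 1, gap = 0)  # everything ties
  m <- run_dp(build_dp_mesh("AAA", "AAA", sc, "nw"))
  a1 <- dp_traceback(m, tie = "random", seed = 1)
  a2 <- dp_traceback(m, tie = "random", seed = 1)
  expect_identical(a1$path, a2$path)
  expect_equal(unname(a1$score), unname(dp_traceback(m)$score))
})

test_that("the affine minus unit charges opening or extension by the selector bit", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1, gap_open = 3, gap_extend = 1)
  r0 <- affine_minus_unit(10, 0, sc, 16)
  expect_identical(un_decode(r0$value), 7L)   # opening charge o = 3
  expect_identical(r0$selector, 1L)
  r1 <- affine_minus_unit(10, 1, sc, 16)
  expect_identical(un_decode(r1$value), 9L)   # extension-only charge g = 1
  expect_identical(r1$selector, 1L)
})

test_that("the affine mesh equals the sequential tagged-bit rule, and collapses to linear when o = g", {
  set.seed(808)
  for (r in 1:30) {
    x <- random_seq(sample(1:8, 1)); y <- random_seq(sample(1:8, 1))
    o <- sample(1:4, 1); e <- sample(0:min(o, 2), 1)
    sc <- scoring_scheme(match = sample(1:4, 1), mismatch = sample(0:2, 1),
                         gap = -e, gap_open = o, gap_extend = e)
    m <- run_dp(build_dp_mesh(x, y, sc, "nw"))
    want <- oracle_affine_tagged(x, y, sc)
    expect_equal(unname(m$C), unname(want$value), ignore_attr = TRUE)
    expect_identical(unname(m$tags), unname(want$tag))
    aln <- dp_traceback(m)  # a consistent path must exist
    expect_identical(degap(aln$x_aln), x)
  }
  for (r in 1:10) {
    x <- random_seq(6); y <- random_seq(6)
    e <- sample(1:2, 1)
    aff <- scoring_scheme(match = 2, mismatch = 0, gap = -e, gap_open = e, gap_extend = e)
    lin <- scoring_scheme(match = 2, mismatch = 0, gap = -e)
    s_aff <- oracle_affine_tagged(x, y, aff)$score
    expect_equal(s_aff, oracle_dp(x, y, lin, "nw")$score)
    expect_equal(s_aff, oracle_gotoh(x, y, aff)$score)
  }
})

test_that("a scaled-scheme alignment rescored under the original scheme recovers the oracle optimum when the shift is zero", {
  set.seed(110)
  for (r in 1:20) {
    x <- random_seq(sample(2:8, 1)); y <- random_seq(sample(2:8, 1))
    sc <- scoring_scheme(match = sample(1:4, 1), mismatch = sample(0:2, 1),
                         gap = -sample(1:2, 1))  # residue scores non-negative
    expect_identical(rmeshalign:::scheme_scale(sc)$beta, 0)
    aln <- rmesh_align(x, y, sc, "nw", engine = "mesh")
    resc <- rescore_original(aln, rmeshalign:::res_matrix(sc), sc$gap)
    # rescoring also charges the leading gap columns that the zero first
    # row/column makes free; discount them before comparing to the oracle
    p <- aln$path
    lead <- sum(p[-1L, 1L] == 0L | p[-1L, 2L] == 0L)
    expect_equal(resc - lead * sc$gap, oracle_dp(x, y, sc, "nw")$score)
  }
})
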