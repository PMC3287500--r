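test_that("scale-up shifts every score by the smallest beta reaching non-negativity", {
  m <- matrix(c(2, -4, -4, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  su <- scale_up(m, -2)
  expect_identical(su$beta, 4)
  expect_identical(su$matrix, m + 4)
  expect_identical(su$gap, 2)
  expect_true(min(c(su$matrix, su$gap)) >= 0)
  idm <- matrix(c(3, 0, 0, 3), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  su0 <- scale_up(idm, 0)
  expect_identical(su0$beta, 0)
  expect_identical(su0$matrix, idm)
})

test_that("the additive shift equals the antilog-multiply-log route", {
  m <- matrix(c(2, -4, -4, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  g <- -2; base <- 2
  beta <- scale_up(m, g)$beta
  # antilog the log-odds scores, multiply by base^beta, take logs again
  round_trip <- log(base^m * base^beta, base = base)
  expect_equal(round_trip, m + beta)
  expect_equal(log(base^g * base^beta, base = base), g + beta)
})

test_that("rescoring an alignment path sums the original scheme over its columns", {
  sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
  ident <- structure(list(x_aln = "AAA", y_aln = "AAA"), class = "rmesh_alignment")
  expect_identical(rescore_original(ident, rmeshalign:::res_matrix(sc), sc$gap), 6)
  gappy <- structure(list(x_aln = "AC-G-", y_aln = "ACTGT"), class = "rmesh_alignment")
  sc1 <- scoring_scheme(match = 1, mismatch = 1, gap = -1)  # 3 matched cols at 1, 2 gaps at -1
  expect_identical(rescore_original(gappy, rmeshalign:::res_matrix(sc1), -1), 1)
  set.seed(12)
  for (r in 1:30) {
    x <- random_seq(sample(2:8, 1)); y <- random_seq(sample(2:8, 1))
    sc2 <- random_scaled_scheme()
    aln <- rmesh_align(x, y, sc2, "nw", engine = "reference")
    xa <- strsplit(aln$x_aln, "")[[1]]; ya <- strsplit(aln$y_aln, "")[[1]]
    direct <- sum(apply(cbind(xa, ya), 1, function(p)
      if (any(p == "-")) sc2$gap else sc2$matrix[p[1], p[2]]))
    expect_equal(rescore_original(aln, rmeshalign:::res_matrix(sc2), sc2$gap), direct)
  }
})

test_that("the merged column pool expands to the worked 15-pair multiset", {
  sp <- sp_pairs(c("A", "C", "T"), c("G", "T", "T"))
  expect_identical(sp$total, 15)
  want <- c("A:C" = 1, "A:G" = 1, "A:T" = 3, "C:G" = 1, "C:T" = 3, "G:T" = 3, "T:T" = 3)
  got <- stats::setNames(sp$pairs$count, paste(sp$pairs$a, sp$pairs$b, sep = ":"))
  expect_identical(got[order(names(got))], want)
  one <- sp_pairs("A", "A")
  expect_identical(one$total, 1)
  expect_identical(one$pairs$count, 1)
  set.seed(5)
  for (r in 1:40) {
    f <- sample(c(DNA, "-"), sample(1:6, 1), replace = TRUE)
    g <- sample(c(DNA, "-"), sample(1:6, 1), replace = TRUE)
    sp <- sp_pairs(f, g)
    expect_equal(sum(sp$pairs$count), sp$total)
    # compare against the explicit double loop
    merged <- c(f, g)
    brute <- table(apply(utils::combn(merged, 2), 2,
                         function(p) paste(sort(p), collapse = ":")))
    got <- stats::setNames(sp$pairs$count, paste(sp$pairs$a, sp$pairs$b, sep = ":"))
    expect_identical(sort(names(got)), sort(names(brute)))
    expect_true(all(got[names(brute)] == as.vector(brute)))
  }
})

test_that("the counting form of sum-of-pairs equals the brute-force definition", {
  ind <- matrix(0, 5, 5, dimnames = list(c(DNA, "-"), c(DNA, "-")))
  ind["T", "T"] <- 1
  expect_identical(sum_of_pair(c("A", "C", "T"), c("G", "T", "T"), ind), 3)
  sc <- scoring_scheme(match = 2, mismatch = -1, gap = -2)
  expect_identical(sum_of_pair("A", "G", sc), sc$matrix["A", "G"])
  set.seed(9)
  for (r in 1:500) {
    f <- sample(c(DNA, "-"), sample(1:10, 1), replace = TRUE)
    g <- sample(c(DNA, "-"), sample(1:10, 1), replace = TRUE)
    M <- matrix(sample(-5:5, 25, replace = TRUE), 5, 5,
                dimnames = list(c(DNA, "-"), c(DNA, "-")))
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    expect_identical(sum_of_pair(f, g, M), oracle_sp(f, g, M))
  }
})

test_that("plain-text substitution matrices parse from the NCBI layout", {
  m <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3,
              dimnames = list(c("A", "C", "G"), c("A", "C", "G")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ncbi_matrix(m, path)
  got <- read_score_matrix(path)
  expect_equal(got, m)
  sc <- scoring_scheme(matrix = got, gap = -2)
  expect_identical(sc$matrix["A", "-"], -2)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# junk", " A C", "A 1", "C 1 x"), bad)
  expect_error(read_score_matrix(bad), "malformed")
})
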