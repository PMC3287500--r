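#' Progressive multiple sequence alignment
#'
#' The classic three-step paradigm, each step running on the simulated mesh
#' or on the sequential reference engine: (i) all pairwise global DP
#' alignments, (ii) a neighbor-joining guide tree from the score matrix,
#' (iii) group-to-group DP alignments in guide-tree order, with sum-of-pairs
#' column scores (counting form) initialising the DP cells.
#'
#' @name progressive
NULL

#' Aligned sequence groups
#'
#' @param x a named character vector of equal-length gapped sequences, or a
#'   character matrix of single symbols (rows = sequences).
#' @return an object of class `aligned_group` wrapping the symbol matrix.
#' @export
aligned_group <- function(x) {
  if (inherits(x, "aligned_group")) return(x)
  if (is.character(x) && !is.matrix(x)) {
    if (length(unique(nchar(x))) > 1L)
      stop("aligned_group: member sequences must have equal length")
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    mat <- do.call(rbind, strsplit(x, ""))
    if (is.null(mat)) mat <- matrix(character(0), length(x), 0L)
    rownames(mat) <- ids
  } else {
    mat <- x
  }
  structure(list(mat = mat), class = "aligned_group")
}

#' @export
print.aligned_group <- function(x, ...) {
  cat(sprintf("aligned group: %d sequences x %d columns\n", nrow(x$mat), ncol(x$mat)))
  s <- apply(x$mat, 1L, paste, collapse = "")
  for (i in seq_along(s)) cat(sprintf(" %-12s %s\n", rownames(x$mat)[i], s[i]))
  invisible(x)
}

#' @rdname aligned_group
#' @param g an `aligned_group`.
#' @return `group_strings` returns the member rows as gapped strings;
#'   `degap` strips the gap symbols.
#' @export
group_strings <- function(g) {
  s <- apply(g$mat, 1L, paste, collapse = "")
  if (!length(s)) s <- character(0)
  stats::setNames(as.character(s), rownames(g$mat))
}

#' @rdname aligned_group
#' @param s gapped sequence strings.
#' @export
degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' All-pairs global alignment scores
#'
#' Step (i): the `m(m-1)/2` pairwise Needleman-Wunsch scores (plus the
#' self-alignment scores on the diagonal), computed on the requested engine.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param scheme a [scoring_scheme()]; scaled automatically if needed.
#' @param engine `"reference"` or `"mesh"`.
#' @return symmetric m x m score matrix.
#' @export
pairwise_all <- function(seqs, scheme = scoring_scheme(), engine = c("reference", "mesh")) {
  engine <- match.arg(engine)
  m <- length(seqs)
  stopifnot(m >= 2L)
  if (min(res_matrix(scheme)) < 0) scheme <- scheme_scale(scheme)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(m))
  S <- matrix(0, m, m, dimnames = list(ids, ids))
  score1 <- function(a, b) {
    if (engine == "mesh") {
      mtx <- run_dp(build_dp_mesh(a, b, scheme, "nw"))
      mtx$C[nchar(a) + 1L, nchar(b) + 1L]
    } else oracle_dp(a, b, scheme, "nw")$score
  }
  for (i in seq_len(m)) for (j in i:m)
    S[i, j] <- S[j, i] <- score1(seqs[[i]], seqs[[j]])
  S
}

# group-level DP scores: diagonal sum-of-pairs matrix (shifted non-negative
# for the unsigned mesh arithmetic -- the same shift is applied on every
# engine, it is part of the algorithm) and the per-column gap-step scores
.group_dp_scores <- function(A, B, scheme) {
  nA <- ncol(A$mat); nB <- ncol(B$mat)
  gapA <- rep("-", nrow(A$mat)); gapB <- rep("-", nrow(B$mat))
  d <- matrix(0, max(nA, 1L), max(nB, 1L))
  if (nA && nB)
    for (i in seq_len(nA)) for (j in seq_len(nB))
      d[i, j] <- sum_of_pair(A$mat[, i], B$mat[, j], scheme)
  gA <- if (nA) vapply(seq_len(nA), function(i) sum_of_pair(A$mat[, i], gapB, scheme), numeric(1)) else numeric(0)
  gB <- if (nB) vapply(seq_len(nB), function(j) sum_of_pair(gapA, B$mat[, j], scheme), numeric(1)) else numeric(0)
  beta_d <- max(0, -min(d))
  list(d = d + beta_d, gA = gA, gB = gB, beta_d = beta_d, nA = nA, nB = nB)
}

# generic group DP over columns: candidates are diag + d[i,j] (non-negative),
# up + gA[i], left + gB[j]; zero boundary; signed on the reference engine,
# 1UN components on the mesh engine
.group_dp_run <- function(sc, engine, w = NULL) {
  nA <- sc$nA; nB <- sc$nB
  C <- matrix(0, nA + 1L, nB + 1L)
  if (engine == "reference") {
    if (nA && nB) for (i in seq_len(nA)) for (j in seq_len(nB))
      C[i + 1L, j + 1L] <- max(C[i, j] + sc$d[i, j],
                               C[i, j + 1L] + sc$gA[i],
                               C[i + 1L, j] + sc$gB[j])
    return(C)
  }
  # mesh engine
  bound <- min(nA, nB) * max(sc$d, 1) + (nA + nB) * max(c(sc$gA, sc$gB, 0)) + 2
  if (is.null(w)) w <- 8L * as.integer(ceiling(bound / 8))
  step <- function(bits, t) {
    if (t >= 0) adder_subtractor(bits, t, "add", w)
    else adder_subtractor(bits, -t, "subtract", w)
  }
  zero <- un_encode(0L, w)
  cells <- vector("list", (nA + 1L) * (nB + 1L))
  dim(cells) <- c(nA + 1L, nB + 1L)
  for (j in 0:nB) cells[[1L, j + 1L]] <- zero
  for (i in 0:nA) cells[[i + 1L, 1L]] <- zero
  if (nA && nB) for (i in seq_len(nA)) for (j in seq_len(nB)) {
    cd <- step(cells[[i, j]], sc$d[i, j])
    cu <- step(cells[[i, j + 1L]], sc$gA[i])
    cl <- step(cells[[i + 1L, j]], sc$gB[j])
    val <- max_switch_nbit(list(cd, cu, cl), w)
    cells[[i + 1L, j + 1L]] <- val
    C[i + 1L, j + 1L] <- un_decode(val)
  }
  C
}

#' Align two pre-aligned groups of sequences
#'
#' Step (iii)'s workhorse: dynamic programming over the columns of the two
#' groups, the cell match score being the counting-form sum-of-pairs of the
#' two columns; a gap step inserts an all-gap column into one group, charged
#' through the same sum-of-pairs with the gap as a symbol type.  With
#' singleton groups this reduces exactly to pairwise DP.  The diagonal
#' scores are shifted non-negative (group-level scale-up) on every engine.
#'
#' @param A,B `aligned_group`s (bare character vectors are wrapped).
#' @param scheme a [scoring_scheme()]; residue scores scaled if needed.
#' @param engine `"reference"` or `"mesh"`.
#' @return the merged `aligned_group` (rows of `A` then rows of `B`), with
#'   the merge score in `attr(, "score")`.
#' @export
group_align <- function(A, B, scheme = scoring_scheme(), engine = c("reference", "mesh")) {
  engine <- match.arg(engine)
  A <- aligned_group(A); B <- aligned_group(B)
  if (min(res_matrix(scheme)) < 0) scheme <- scheme_scale(scheme)
  sc <- .group_dp_scores(A, B, scheme)
  C <- .group_dp_run(sc, engine)
  # trace back, ties diagonal > up > left, through the zero boundary to (0,0)
  i <- sc$nA; j <- sc$nB
  steps <- character(0)
  while (i > 0L || j > 0L) {
    mv <- if (i > 0L && j > 0L) {
      here <- C[i + 1L, j + 1L]
      if (isTRUE(all.equal(here, C[i, j] + sc$d[i, j]))) "diag"
      else if (isTRUE(all.equal(here, C[i, j + 1L] + sc$gA[i]))) "up"
      else if (isTRUE(all.equal(here, C[i + 1L, j] + sc$gB[j]))) "left"
      else stop("group_align: inconsistent group DP matrix")
    } else if (i > 0L) "up" else "left"
    if (mv == "diag") { i <- i - 1L; j <- j - 1L }
    else if (mv == "up") i <- i - 1L
    else j <- j - 1L
    steps <- c(mv, steps)
  }
  gapA <- rep("-", nrow(A$mat)); gapB <- rep("-", nrow(B$mat))
  cols <- vector("list", length(steps))
  ii <- 0L; jj <- 0L
  for (t in seq_along(steps)) {
    cols[[t]] <- switch(steps[t],
      diag = { ii <- ii + 1L; jj <- jj + 1L; c(A$mat[, ii], B$mat[, jj]) },
      up   = { ii <- ii + 1L; c(A$mat[, ii], gapB) },
      left = { jj <- jj + 1L; c(gapA, B$mat[, jj]) })
  }
  mat <- if (length(cols)) do.call(cbind, cols)
         else matrix(character(0), nrow(A$mat) + nrow(B$mat), 0L)
  rownames(mat) <- c(rownames(A$mat), rownames(B$mat))
  out <- aligned_group(mat)
  attr(out, "score") <- C[sc$nA + 1L, sc$nB + 1L]
  attr(out, "beta_d") <- sc$beta_d
  out
}

#' End-to-end progressive multiple sequence alignment
#'
#' Runs the full pipeline: scale the scheme, compute all pairwise scores,
#' build the neighbor-joining guide tree from the score-derived distances,
#' then perform the `m - 1` group merges in guide-tree order (children are
#' always merged before their parent).  The output rows keep the input
#' order; stripping the gaps recovers the inputs exactly.
#'
#' @param seqs named character vector of `m >= 2` unaligned sequences.
#' @param scheme a [scoring_scheme()].
#' @param engine `"reference"` (sequential, the default) or `"mesh"`
#'   (simulated r-mesh; intended for small inputs).
#' @return an object of class `msa_result`: the `alignment` (named gapped
#'   strings in input order), the `tree`, per-merge `merge_scores`, the
#'   pairwise `scores` and `distances`, the scaled `scheme`, and a
#'   `resource_log` with the processing-unit accounting.
#' @examples
#' fam <- synth_family(m = 4, n = 10, seed = 7)
#' progressive_msa(fam$seqs, scoring_scheme(match = 2, mismatch = 0, gap = -1))
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme(),
                            engine = c("reference", "mesh")) {
  engine <- match.arg(engine)
  m <- length(seqs)
  stopifnot(m >= 2L)
  ids <- names(seqs)
  if (is.null(ids)) { ids <- paste0("seq", seq_len(m)); names(seqs) <- ids }
  if (min(res_matrix(scheme)) < 0) scheme <- scheme_scale(scheme)
  S <- pairwise_all(seqs, scheme, engine)
  D <- distances_from_scores(S)
  tree <- nj_build(D)
  groups <- vector("list", 2L * m - 1L)
  for (i in seq_len(m)) groups[[i]] <- aligned_group(seqs[i])
  merge_scores <- numeric(nrow(tree$merges))
  for (t in seq_len(nrow(tree$merges))) {
    mg <- tree$merges[t, ]
    merged <- group_align(groups[[mg$left]], groups[[mg$right]], scheme, engine)
    groups[[mg$node]] <- merged
    merge_scores[t] <- attr(merged, "score")
  }
  final <- groups[[2L * m - 1L]]
  aln <- group_strings(final)[ids]
  n <- max(nchar(seqs))
  structure(list(alignment = aln, tree = tree, merge_scores = merge_scores,
                 scores = S, distances = D, scheme = scheme, engine = engine,
                 resource_log = msa_resource_log(n, m, scheme)),
            class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("progressive MSA of %d sequences (%s engine)\n",
              length(x$alignment), x$engine))
  for (i in seq_along(x$alignment))
    cat(sprintf(" %-12s %s\n", names(x$alignment)[i], x$alignment[i]))
  cat("guide tree: ", write_newick(x$tree), "\n", sep = "")
  cat("merge scores:", paste(format(x$merge_scores), collapse = ", "), "\n")
  invisible(x)
}
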