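#' Neighbor-joining guide trees
#'
#' The progressive aligner orders its merges by a neighbor-joining dendrogram
#' built from the pairwise alignment scores.  The construction follows the
#' classic five steps: from the m x m distance matrix compute the net
#' divergences `r_i = sum_j D_ij / (m - 2)`, join the pair minimising
#' `M_ij = D_ij - r_i - r_j`, assign branch lengths
#' `d_iu = D_ij/2 + (r_i - r_j)/2`, `d_ju = D_ij - d_iu`, and update the
#' distances to the new node; `m - 1` joins reduce the matrix to a single
#' root.
#'
#' @name guide_tree
NULL

#' Convert pairwise alignment scores to distances
#'
#' Higher alignment scores mean closer sequences; the guide tree needs
#' distances, so scores are reflected about the matrix maximum:
#' `D_ij = max(S) - S_ij`, `D_ii = 0`.  Any monotone-decreasing transform
#' gives the same join order; this one keeps the matrix non-negative and
#' integral for integral scores.
#'
#' @param S symmetric score matrix (diagonal = self-alignment scores).
#' @return a non-negative symmetric distance matrix with zero diagonal.
#' @export
distances_from_scores <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  D <- max(S) - S
  diag(D) <- 0
  dimnames(D) <- dimnames(S)
  D
}

#' Build a neighbor-joining guide tree
#'
#' Joins are selected by minimising `M_ij`; for numerical robustness the
#' comparison uses the equivalent integer-exact form
#' `(m - 2) D_ij - sum_v D_iv - sum_v D_jv`.  Ties resolve to the pair with
#' the shortest distance `D_ij`, then to the lexicographically smallest label
#' pair.  With two nodes left (including the
#' degenerate `m = 2` input, where `r` is undefined) the pair joins directly
#' with half the remaining distance on each branch.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal
#'   (`m >= 2`); row names label the leaves (defaults to `t1..tm`).
#' @param literal_update use the alternative distance update
#'   `D_vu = D_iv + D_jv - D_ij` instead of the standard Saitou-Nei form
#'   `(D_iv + D_jv - D_ij)/2`.  This form drops the 1/2 factor of the standard derivation; the
#'   standard form is the default.
#' @return an object of class `guide_tree`: `merges` (one row per join, in
#'   merge order: child node ids, branch lengths, new node id), `labels`, and
#'   `m`.  Leaves are nodes `1..m`, internal nodes `m+1..2m-1`.
#' @examples
#' D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4)
#' rownames(D) <- colnames(D) <- c("a", "b", "c", "d")
#' nj_build(D)
#' @export
nj_build <- function(D, literal_update = FALSE) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  m <- nrow(D)
  if (m < 2L) stop("nj_build: need at least 2 nodes")
  if (any(abs(D - t(D)) > 1e-9) || any(diag(D) != 0))
    stop("nj_build: distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(m))
  nodes <- seq_len(m)           # active node ids
  labs <- labels                # labels of active nodes (internal: smallest leaf label)
  A <- D
  nextid <- m + 1L
  merges <- list()
  while (length(nodes) > 2L) {
    mm <- length(nodes)
    rsum <- rowSums(A)
    # (m-2) M_ij, exact for integral distances
    Ms <- (mm - 2) * A - outer(rsum, rsum, `+`)
    diag(Ms) <- Inf
    best <- min(Ms)
    cand <- which(Ms - best <= 1e-9 & upper.tri(Ms), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      dv <- A[cand]
      key <- apply(cand, 1L, function(rc) {
        p <- sort(c(labs[rc[1L]], labs[rc[2L]]))
        paste(p, collapse = "\r")
      })
      cand <- cand[order(dv, key)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    ri <- rsum[i] / (mm - 2); rj <- rsum[j] / (mm - 2)
    diu <- A[i, j] / 2 + (ri - rj) / 2
    dju <- A[i, j] - diu
    u <- nextid; nextid <- nextid + 1L
    merges[[length(merges) + 1L]] <-
      data.frame(node = u, left = nodes[i], right = nodes[j],
                 d_left = diu, d_right = dju)
    newd <- if (literal_update) A[i, ] + A[j, ] - A[i, j]
            else (A[i, ] + A[j, ] - A[i, j]) / 2
    newd <- newd[-c(i, j)]
    keep <- setdiff(seq_along(nodes), c(i, j))
    A <- rbind(cbind(A[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    nodes <- c(nodes[keep], u)
    labs <- c(labs[keep], min(labs[c(i, j)]))
    dimnames(A) <- list(labs, labs)
  }
  # final pair joins directly (r is undefined at m = 2)
  u <- nextid
  merges[[length(merges) + 1L]] <-
    data.frame(node = u, left = nodes[1L], right = nodes[2L],
               d_left = A[1L, 2L] / 2, d_right = A[1L, 2L] / 2)
  structure(list(merges = do.call(rbind, merges), labels = labels, m = m),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("neighbor-joining guide tree over %d sequences (%d merges)\n",
              x$m, nrow(x$merges)))
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Write a guide tree in Newick format
#'
#' @param tree a [nj_build()] guide tree.
#' @param file optional path to write to; otherwise the string is returned.
#' @param branch_lengths include branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, branch_lengths = TRUE) {
  mg <- tree$merges
  fmt <- function(node) {
    if (node <= tree$m) return(tree$labels[node])
    row <- mg[mg$node == node, ]
    bl <- function(d) if (branch_lengths) sprintf(":%g", d) else ""
    sprintf("(%s%s,%s%s)", fmt(row$left), bl(row$d_left),
            fmt(row$right), bl(row$d_right))
  }
  s <- paste0(fmt(mg$node[nrow(mg)]), ";")
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Convert a guide tree to an ape-style "phylo" object
#'
#' Builds the `edge`/`edge.length`/`tip.label` structure used by the ape
#' package (tips `1..m`, root `m + 1`), without requiring ape itself.
#'
#' @param tree a [nj_build()] guide tree.
#' @return an object of class `phylo`.
#' @export
to_phylo <- function(tree) {
  m <- tree$m
  # internal ids m+1..2m-1 in merge order; phylo wants the root to be m+1
  remap <- function(v) ifelse(v <= m, v, 3L * m - v)
  mg <- tree$merges
  edge <- rbind(cbind(remap(mg$node), remap(mg$left)),
                cbind(remap(mg$node), remap(mg$right)))
  len <- c(mg$d_left, mg$d_right)
  structure(list(edge = edge, edge.length = len,
                 tip.label = tree$labels, Nnode = m - 1L),
            class = "phylo", order = NULL)
}
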