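#' Independent sequential reference implementations
#'
#' Direct transcriptions of the textbook recurrences and procedures, used as
#' ground truth when validating the mesh constructions.  They use plain
#' signed integers (no 1UN representation) and share no code with the mesh
#' modules; a mesh-vs-oracle mismatch is a defect by definition.
#'
#' @name oracles
NULL

.chars <- function(s) if (length(s) == 1L && is.character(s)) strsplit(s, "")[[1L]] else as.character(s)

#' Sequential dynamic-programming oracle
#'
#' Fills the (n+1) x (n+1) score matrix with the classic recurrences, zero
#' first row and column, row-major:
#' Needleman-Wunsch `c = max(diag + s, up + g, left + g)`;
#' Smith-Waterman additionally floors at `scheme$beta` (0 when unscaled);
#' LCS scores `diag + 1` on a match and `max(up, left)` otherwise.
#'
#' @param x,y sequences (strings or character vectors).
#' @param scheme a [scoring_scheme()]; ignored for `mode = "lcs"`.
#' @param mode `"nw"`, `"sw"` or `"lcs"`.
#' @return list with the score `matrix` (dimnames are 0-based indices),
#'   `score` (at `c[n,n]` for NW/LCS, the matrix maximum for SW) and `mode`.
#' @export
oracle_dp <- function(x, y, scheme = scoring_scheme(), mode = c("nw", "sw", "lcs")) {
  mode <- match.arg(mode)
  xc <- .chars(x); yc <- .chars(y)
  nx <- length(xc); ny <- length(yc)
  C <- matrix(0, nx + 1L, ny + 1L,
              dimnames = list(0:nx, 0:ny))
  g <- scheme$gap
  floor <- if (mode == "sw") scheme$beta else -Inf
  if (nx > 0L && ny > 0L) for (i in 1:nx) for (j in 1:ny) {
    if (mode == "lcs") {
      C[i + 1L, j + 1L] <- if (xc[i] == yc[j]) C[i, j] + 1 else max(C[i, j + 1L], C[i + 1L, j])
    } else {
      s <- scheme$matrix[xc[i], yc[j]]
      C[i + 1L, j + 1L] <- max(floor, C[i, j] + s, C[i, j + 1L] + g, C[i + 1L, j] + g)
    }
  }
  score <- if (mode == "sw") max(C) else C[nx + 1L, ny + 1L]
  list(matrix = C, score = score, mode = mode)
}

#' Sequential oracle for the tagged-bit affine gap rule
#'
#' Every cell carries a value and a one-bit selector telling whether the
#' value has already been gap-penalized.  Gap-sourced candidates charge the
#' full opening cost `o` when the incoming tag is 0 and only the extension
#' cost `g` when it is 1, and always leave with tag 1; diagonal candidates
#' add the substitution score and carry tag 0.  The cell keeps the maximal
#' candidate; its tag is the OR of the tags of all maximal candidates.
#'
#' @param x,y sequences.
#' @param scheme a [scoring_scheme()] with affine costs set.
#' @return list with `value` and `tag` matrices and the `score` at `c[n,n]`.
#' @export
oracle_affine_tagged <- function(x, y, scheme) {
  stopifnot(!is.null(scheme$affine))
  o <- scheme$affine$open; e <- scheme$affine$extend
  xc <- .chars(x); yc <- .chars(y)
  nx <- length(xc); ny <- length(yc)
  V <- matrix(0, nx + 1L, ny + 1L)
  Tg <- matrix(0L, nx + 1L, ny + 1L)
  am <- function(v, t) if (t == 1L) max(v - o, v - e) else v - o
  if (nx > 0L && ny > 0L) for (i in 1:nx) for (j in 1:ny) {
    cand <- c(V[i, j] + scheme$matrix[xc[i], yc[j]],
              am(V[i, j + 1L], Tg[i, j + 1L]),
              am(V[i + 1L, j], Tg[i + 1L, j]))
    tags <- c(0L, 1L, 1L)
    best <- max(cand)
    V[i + 1L, j + 1L] <- best
    Tg[i + 1L, j + 1L] <- as.integer(any(tags[cand == best] == 1L))
  }
  list(value = V, tag = Tg, score = V[nx + 1L, ny + 1L])
}

#' Gotoh three-matrix affine oracle
#'
#' The standard affine-gap dynamic program with matrices M (match), Ix and
#' Iy (gap in x / y), zero boundary on the overall score, used as the
#' established comparison point for the tagged-bit scheme.
#'
#' @param x,y sequences.
#' @param scheme a [scoring_scheme()] with affine costs set.
#' @return list with the overall score matrix `H` and `score` at `c[n,n]`.
#' @export
oracle_gotoh <- function(x, y, scheme) {
  stopifnot(!is.null(scheme$affine))
  o <- scheme$affine$open; e <- scheme$affine$extend
  xc <- .chars(x); yc <- .chars(y)
  nx <- length(xc); ny <- length(yc)
  H <- matrix(0, nx + 1L, ny + 1L)
  Ix <- matrix(-Inf, nx + 1L, ny + 1L)
  Iy <- matrix(-Inf, nx + 1L, ny + 1L)
  if (nx > 0L && ny > 0L) for (i in 1:nx) for (j in 1:ny) {
    Ix[i + 1L, j + 1L] <- max(H[i, j + 1L] - o, Ix[i, j + 1L] - e)
    Iy[i + 1L, j + 1L] <- max(H[i + 1L, j] - o, Iy[i + 1L, j] - e)
    H[i + 1L, j + 1L] <- max(H[i, j] + scheme$matrix[xc[i], yc[j]],
                             Ix[i + 1L, j + 1L], Iy[i + 1L, j + 1L])
  }
  list(H = H, score = H[nx + 1L, ny + 1L])
}

#' Brute-force sum-of-pairs oracle
#'
#' Explicit double loop over all unordered pairs of the merged residue pool
#' of the two columns.
#'
#' @param f,g character vectors of residue symbols.
#' @param matrix full substitution matrix (dimnames covering every symbol,
#'   including `-` when present), or a [scoring_scheme()].
#' @return the sum-of-pairs score.
#' @export
oracle_sp <- function(f, g, matrix) {
  if (inherits(matrix, "scoring_scheme")) matrix <- matrix$matrix
  merged <- c(f, g)
  n <- length(merged)
  total <- 0
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    total <- total + matrix[merged[i], merged[j]]
  total
}

#' Flood-fill bus oracle
#'
#' Independent breadth-first search over the port graph of a mesh (intra-unit
#' fusions plus grid adjacency); used to cross-check [resolve_buses()].
#'
#' @param mesh a [mesh_config()].
#' @return list of buses, each a sorted character vector of `"r,c,P"` port
#'   keys, ordered by their first key.
#' @export
oracle_flood_fill <- function(mesh) {
  units <- mesh_units(mesh)
  keys <- names(units)
  adj <- new.env(parent = emptyenv())
  addedge <- function(a, b) {
    assign(a, c(if (exists(a, envir = adj, inherits = FALSE)) get(a, envir = adj), b), envir = adj)
    assign(b, c(if (exists(b, envir = adj, inherits = FALSE)) get(b, envir = adj), a), envir = adj)
  }
  allports <- character(0)
  for (k in seq_along(keys)) {
    rc <- strsplit(keys[k], ",", fixed = TRUE)[[1L]]
    r <- as.integer(rc[1L]); c <- as.integer(rc[2L])
    pk <- paste0(r, ",", c, ",", c("N", "S", "E", "W"))
    allports <- c(allports, pk)
    for (grp in units[[k]]) {
      if (length(grp) > 1L) for (t in 2:length(grp))
        addedge(paste0(r, ",", c, ",", grp[1L]), paste0(r, ",", c, ",", grp[t]))
    }
    if (paste0(r, ",", c + 1L) %in% keys)
      addedge(paste0(r, ",", c, ",E"), paste0(r, ",", c + 1L, ",W"))
    if (paste0(r + 1L, ",", c) %in% keys)
      addedge(paste0(r, ",", c, ",S"), paste0(r + 1L, ",", c, ",N"))
  }
  seen <- new.env(parent = emptyenv())
  buses <- list()
  for (p in allports) {
    if (exists(p, envir = seen, inherits = FALSE)) next
    queue <- p
    comp <- character(0)
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      if (exists(q, envir = seen, inherits = FALSE)) next
      assign(q, TRUE, envir = seen)
      comp <- c(comp, q)
      if (exists(q, envir = adj, inherits = FALSE))
        queue <- c(queue, get(q, envir = adj))
    }
    buses[[length(buses) + 1L]] <- sort(comp)
  }
  buses[order(vapply(buses, `[`, character(1), 1L))]
}

#' Linear-scan argmax oracle
#'
#' @param C a numeric matrix.
#' @return 0-based `(i, j)` of the maximum, ties broken by the
#'   lexicographically smallest `(i, j)`.
#' @export
oracle_argmax <- function(C) {
  best <- -Inf; bi <- 0L; bj <- 0L
  for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
    if (C[i, j] > best) { best <- C[i, j]; bi <- i; bj <- j }
  }
  c(i = bi - 1L, j = bj - 1L)
}

# ---- exponential brute force (the oracle of the oracle) ----------------

# best global score by explicit recursion over every alignment; leading gap
# runs are free, matching the zero first row/column initialization
brute_force_nw <- function(x, y, scheme) {
  xc <- .chars(x); yc <- .chars(y)
  g <- scheme$gap
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    cand <- if (i == 0L || j == 0L) 0 else -Inf  # stop: remaining prefix is free
    if (i > 0L && j > 0L)
      cand <- max(cand, rec(i - 1L, j - 1L) + scheme$matrix[xc[i], yc[j]])
    if (i > 0L) cand <- max(cand, rec(i - 1L, j) + g)
    if (j > 0L) cand <- max(cand, rec(i, j - 1L) + g)
    cand
  }
  rec(length(xc), length(yc))
}

# longest common subsequence by enumerating every subsequence of the shorter
# string and testing membership in the other
brute_force_lcs <- function(x, y) {
  xc <- .chars(x); yc <- .chars(y)
  if (length(xc) > length(yc)) { tmp <- xc; xc <- yc; yc <- tmp }
  n <- length(xc)
  is_subseq <- function(s, t) {
    ti <- 1L
    for (ch in s) {
      while (ti <= length(t) && t[ti] != ch) ti <- ti + 1L
      if (ti > length(t)) return(FALSE)
      ti <- ti + 1L
    }
    TRUE
  }
  best <- 0L
  if (n > 0L) for (mask in 0:(2^n - 1L)) {
    sub <- xc[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L]
    if (length(sub) > best && is_subseq(sub, yc)) best <- length(sub)
  }
  best
}

# ---- independently coded sequential progressive MSA --------------------

#' Sequential progressive MSA reference
#'
#' A self-contained, plainly sequential implementation of the whole
#' progressive pipeline -- pairwise scoring, neighbor joining, group merges
#' with brute-force sum-of-pairs -- sharing no code with the mesh modules or
#' the package pipeline, but following the same stated tie policies
#' (lexicographic NJ ties, diagonal > up > left trace ties, non-negative
#' shift of the group diagonal scores).  Used to validate
#' [progressive_msa()] end to end.
#'
#' @param seqs named character vector of sequences.
#' @param scheme a [scoring_scheme()].
#' @return named character vector: the gapped alignment in input order.
#' @export
oracle_progressive <- function(seqs, scheme = scoring_scheme()) {
  m <- length(seqs)
  stopifnot(m >= 2L)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(m))
  # scale the residue scores non-negative (part of the algorithm's contract)
  a <- scheme$alphabet
  rm <- scheme$matrix[a, a]
  shift <- max(0, -min(rm))
  scheme$matrix[a, a] <- rm + shift
  scheme$beta <- shift
  # step (i): pairwise global scores
  S <- matrix(0, m, m)
  for (i in 1:m) for (j in i:m)
    S[i, j] <- S[j, i] <- oracle_dp(seqs[[i]], seqs[[j]], scheme, "nw")$score
  D <- max(S) - S
  diag(D) <- 0
  # step (ii): neighbor joining (standard update), lexicographic tie rule
  act_mat <- lapply(seq_len(m), function(i) {
    mt <- matrix(.chars(seqs[[i]]), 1L)
    rownames(mt) <- ids[i]
    mt
  })
  act_lab <- ids
  A <- D
  while (length(act_mat) > 1L) {
    mm <- length(act_mat)
    if (mm == 2L) {
      pick <- c(1L, 2L)
    } else {
      rsum <- rowSums(A)
      best <- Inf; bestd <- Inf; pick <- NULL; bestkey <- NULL
      for (i in 1:(mm - 1L)) for (j in (i + 1L):mm) {
        ms <- (mm - 2) * A[i, j] - rsum[i] - rsum[j]
        key <- paste(sort(c(act_lab[i], act_lab[j])), collapse = "\r")
        better <- ms < best - 1e-9 ||
          (abs(ms - best) <= 1e-9 &&
             (A[i, j] < bestd - 1e-9 ||
                (abs(A[i, j] - bestd) <= 1e-9 && key < bestkey)))
        if (better) { best <- ms; bestd <- A[i, j]; pick <- c(i, j); bestkey <- key }
      }
    }
    i <- pick[1L]; j <- pick[2L]
    # step (iii) merge: group DP over columns with brute-force SP scores
    merged <- .oracle_group_merge(act_mat[[i]], act_mat[[j]], scheme)
    keep <- setdiff(seq_len(mm), pick)
    newd <- if (mm > 2L) (A[i, keep] + A[j, keep] - A[i, j]) / 2 else numeric(0)
    A <- rbind(cbind(A[keep, keep, drop = FALSE], newd), c(newd, 0))
    act_mat <- c(act_mat[keep], list(merged))
    act_lab <- c(act_lab[keep], min(act_lab[c(i, j)]))
  }
  out <- apply(act_mat[[1L]], 1L, paste, collapse = "")
  out[ids]
}

.oracle_group_merge <- function(MA, MB, scheme) {
  nA <- ncol(MA); nB <- ncol(MB)
  full <- scheme$matrix
  gapA <- rep("-", nrow(MA)); gapB <- rep("-", nrow(MB))
  d <- matrix(0, max(nA, 1L), max(nB, 1L))
  if (nA && nB) for (i in 1:nA) for (j in 1:nB)
    d[i, j] <- oracle_sp(MA[, i], MB[, j], full)
  d <- d + max(0, -min(d))
  gA <- if (nA) vapply(1:nA, function(i) oracle_sp(MA[, i], gapB, full), numeric(1)) else numeric(0)
  gB <- if (nB) vapply(1:nB, function(j) oracle_sp(gapA, MB[, j], full), numeric(1)) else numeric(0)
  C <- matrix(0, nA + 1L, nB + 1L)
  if (nA && nB) for (i in 1:nA) for (j in 1:nB)
    C[i + 1L, j + 1L] <- max(C[i, j] + d[i, j], C[i, j + 1L] + gA[i], C[i + 1L, j] + gB[j])
  i <- nA; j <- nB
  cols <- list()
  while (i > 0L || j > 0L) {
    mv <- if (i > 0L && j > 0L) {
      here <- C[i + 1L, j + 1L]
      if (isTRUE(all.equal(here, C[i, j] + d[i, j]))) "diag"
      else if (isTRUE(all.equal(here, C[i, j + 1L] + gA[i]))) "up"
      else "left"
    } else if (i > 0L) "up" else "left"
    col <- switch(mv,
                  diag = c(MA[, i], MB[, j]),
                  up   = c(MA[, i], gapB),
                  left = c(gapA, MB[, j]))
    cols <- c(list(col), cols)
    if (mv != "left") i <- i - 1L
    if (mv != "up") j <- j - 1L
  }
  out <- if (length(cols)) do.call(cbind, cols)
         else matrix(character(0), nrow(MA) + nrow(MB), 0L)
  rownames(out) <- c(rownames(MA), rownames(MB))
  out
}
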