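#' The constant-time dynamic-programming alignment mesh
#'
#' Each DP cell `c[i,j]` combines three adder/subtractor units and a 3-input
#' max switch: the diagonal path adds the (scaled, non-negative) substitution
#' score, the vertical and horizontal paths subtract the gap magnitude, and
#' the switch propagates the maximum onward.  Values flow down and to the
#' right only, so the assembly is simulated component-by-component in
#' topological order with port-level value passing -- functionally equivalent
#' to the single-broadcast flat grid, whose inter-component routing is not
#' specified at bit level.  Resource accounting still
#' reports the flat totals.
#'
#' @name dp_mesh
NULL

#' Build a DP alignment mesh assembly
#'
#' @param x,y sequences (strings or character vectors).
#' @param scheme a [scoring_scheme()].  For `"nw"`/`"sw"` the residue
#'   substitution scores must already be non-negative (scale first, e.g. with
#'   [scale_up()] or via [rmesh_align()] which scales automatically) and the
#'   linear gap score must be `<= 0`; the LCS mode fixes the scores to
#'   +1/match, 0/mismatch, gap cost 0.
#' @param mode `"nw"`, `"sw"` or `"lcs"`.
#' @param w 1UN bit width; defaults to the smallest multiple of 8 that holds
#'   the maximum attainable score plus one.
#' @return an object of class `dp_assembly`.
#' @export
build_dp_mesh <- function(x, y, scheme = scoring_scheme(), mode = c("nw", "sw", "lcs"),
                          w = NULL) {
  mode <- match.arg(mode)
  xc <- .chars(x); yc <- .chars(y)
  nx <- length(xc); ny <- length(yc)
  affine <- !is.null(scheme$affine) && mode != "lcs"
  if (mode == "lcs") {
    sd <- outer(xc, yc, `==`) * 1L
    p <- 0L
  } else {
    if (!all(c(xc, yc) %in% scheme$alphabet))
      stop("build_dp_mesh: sequence symbol outside the scheme alphabet")
    if (min(res_matrix(scheme)) < 0)
      stop("build_dp_mesh: substitution scores must be scaled non-negative for the mesh")
    if (scheme$gap > 0)
      stop("build_dp_mesh: linear gap score must be <= 0")
    sd <- matrix(0L, max(nx, 1L), max(ny, 1L))
    if (nx > 0L && ny > 0L)
      sd <- outer(xc, yc, function(a, b) scheme$matrix[cbind(a, b)])
    p <- if (affine) scheme$affine$extend else -scheme$gap
  }
  floor <- if (mode == "sw") scheme$beta else NULL
  max_attain <- max(min(nx, ny) * max(sd, 1), if (!is.null(floor)) floor else 0)
  w_needed <- as.integer(max_attain + 2L)
  if (is.null(w)) w <- 8L * ceiling(w_needed / 8) else w <- as.integer(w)
  if (w < w_needed)
    stop(sprintf("build_dp_mesh: capacity error, width %d cannot hold the maximum attainable score %d",
                 w, max_attain))
  # flat processing-unit totals of the simulated components
  pu_cell <- function(i, j) {
    base <- 4L * w + w * (sd[i, j] + 2L * p)
    if (affine) {
      eps <- scheme$affine$eps
      base <- base + 2L * (w * eps + w * (w + 1L) + w)  # two affine minus units
    }
    base
  }
  pu_actual <- 0L
  if (nx > 0L && ny > 0L)
    pu_actual <- sum(outer(seq_len(nx), seq_len(ny), Vectorize(pu_cell)))
  structure(list(x = paste(xc, collapse = ""), y = paste(yc, collapse = ""),
                 xc = xc, yc = yc, nx = nx, ny = ny,
                 mode = mode, scheme = scheme, affine = affine,
                 sd = sd, p = p, floor = floor, w = w,
                 pu = pu_actual),
            class = "dp_assembly")
}

#' @export
pu_count.dp_assembly <- function(x, ...) x$pu

#' @export
print.dp_assembly <- function(x, ...) {
  cat(sprintf("DP r-mesh assembly (%s): %d x %d cells, width %d, %d simulated PUs\n",
              toupper(x$mode), x$nx, x$ny, x$w, x$pu))
  invisible(x)
}

# affine gap unit evaluated through mesh components: subtract the extension,
# then either charge the extra opening eps or (if already gap-penalized,
# selector 1) admit the un-eps-charged branch through the on/off switch and
# let a 2-input max pick the larger; output is always tagged 1
.affine_minus_mesh <- function(bits, selector, scheme, w) {
  e <- scheme$affine$extend; eps <- scheme$affine$eps
  v1 <- adder_subtractor(bits, e, "subtract", w)
  v2 <- adder_subtractor(v1, eps, "subtract", w)
  gated <- if (un_is_underflow(v1)) v1 else on_off_switch(v1, selector, w)
  out <- max_switch_nbit(list(v2, gated, un_underflow(w)), w)
  list(value = out, selector = 1L)
}

#' The affine gap "minus" unit
#'
#' Applies a gap charge to a tagged 1UN value: values not yet gap-penalized
#' (selector 0) are charged the full opening cost `o`; already-penalized
#' values (selector 1) are charged only the extension cost `g`, because the
#' on/off switch admits the branch without the extra `eps = o - g` charge and
#' the 2-input max switch selects the larger.  The output selector is always
#' 1.
#'
#' @param value a 1UN bit vector of width `w`, or a non-negative integer.
#' @param selector the incoming tag bit (1 = already gap-penalized).
#' @param scheme a [scoring_scheme()] with affine costs.
#' @param w bit width.
#' @return list with elements `value` (1UN bits) and `selector` (always 1).
#' @examples
#' sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1, gap_open = 3, gap_extend = 1)
#' un_decode(affine_minus_unit(10, 0, sc, 16)$value)  # 7  (opening charge o = 3)
#' un_decode(affine_minus_unit(10, 1, sc, 16)$value)  # 9  (extension charge g = 1)
#' @export
affine_minus_unit <- function(value, selector, scheme, w) {
  stopifnot(!is.null(scheme$affine))
  if (length(value) == 1L && !is.na(value) && value >= 0L) value <- un_encode(value, w)
  .affine_minus_mesh(value, as.integer(selector), scheme, w)
}

#' LCS cell wiring
#'
#' The LCS variant of the DP cell: the South-East unit of the 4-way switch
#' configures \{NS,E,W\} when the symbols at row `i` and column `j` differ
#' (the max of the up/left values passes) and \{N,E,SW\} when they match
#' (the diagonal value, incremented by 1, passes).  The gap cost is fixed to
#' zero.
#'
#' @param match logical: are the two symbols equal?
#' @return list with the South-East unit `partition` and the fixed `gap`.
#' @export
lcs_cell_config <- function(match) {
  list(partition = if (match) "N|E|SW" else "NS|E|W", gap = 0L)
}

# one LCS cell evaluated through mesh components
.lcs_cell_mesh <- function(diag, up, left, match, w) {
  if (match) adder_subtractor(diag, 1L, "add", w)
  else max_switch_nbit(list(up, left, un_underflow(w)), w)
}

#' Run a DP mesh assembly
#'
#' Activates the assembly: boundary cells are held at zero and every interior
#' cell is evaluated through its adder/subtractor and max-switch components
#' in topological (row-major) order, the 1UN values passing between cells at
#' port level.  Underflowed (all-zero) gap candidates are never selected over
#' a valid encoding; in Smith-Waterman mode the floor value (`beta` for
#' scaled schemes, else 0) enters the max switch as a fourth input.
#'
#' @param assembly a [build_dp_mesh()] assembly.
#' @return an object of class `dp_matrix`: the decoded score matrix `C`
#'   (0-based dimnames), affine `tags` when applicable, and the assembly
#'   metadata.
#' @export
run_dp <- function(assembly) {
  stopifnot(inherits(assembly, "dp_assembly"))
  nx <- assembly$nx; ny <- assembly$ny; w <- assembly$w
  mode <- assembly$mode; scheme <- assembly$scheme
  zero <- un_encode(0L, w)
  cells <- vector("list", (nx + 1L) * (ny + 1L))
  dim(cells) <- c(nx + 1L, ny + 1L)
  for (j in 0:ny) cells[[1L, j + 1L]] <- zero
  for (i in 0:nx) cells[[i + 1L, 1L]] <- zero
  tags <- if (assembly$affine) matrix(0L, nx + 1L, ny + 1L) else NULL
  floor_bits <- if (!is.null(assembly$floor)) un_encode(assembly$floor, w) else NULL
  if (nx > 0L && ny > 0L) for (i in 1:nx) for (j in 1:ny) {
    dg <- cells[[i, j]]; up <- cells[[i, j + 1L]]; lf <- cells[[i + 1L, j]]
    if (mode == "lcs") {
      val <- .lcs_cell_mesh(dg, up, lf, assembly$sd[i, j] == 1L, w)
    } else if (!assembly$affine) {
      cd <- adder_subtractor(dg, assembly$sd[i, j], "add", w)
      cu <- adder_subtractor(up, assembly$p, "subtract", w)
      cl <- adder_subtractor(lf, assembly$p, "subtract", w)
      ins <- list(cd, cu, cl)
      if (!is.null(floor_bits)) ins <- c(ins, list(floor_bits))
      val <- max_switch_nbit(ins, w)
    } else {
      cd <- adder_subtractor(dg, assembly$sd[i, j], "add", w)
      au <- .affine_minus_mesh(up, tags[i, j + 1L], scheme, w)
      al <- .affine_minus_mesh(lf, tags[i + 1L, j], scheme, w)
      ins <- list(cd, au$value, al$value)
      if (!is.null(floor_bits)) ins <- c(ins, list(floor_bits))
      val <- max_switch_nbit(ins, w)
      # the cell's unit keeps the selector of the winning candidate locally;
      # ties between a diagonal and a gap candidate OR the tag bits
      vdec <- un_decode(val)
      cand_val <- vapply(ins[1:3], function(b) {
        d <- un_decode(b); if (is.na(d)) -1L else d
      }, numeric(1))
      cand_tag <- c(0L, 1L, 1L)
      tags[i + 1L, j + 1L] <- as.integer(any(cand_tag[cand_val == vdec] == 1L))
    }
    cells[[i + 1L, j + 1L]] <- val
  }
  C <- matrix(vapply(cells, function(b) {
    d <- un_decode(b); if (is.na(d)) NA_integer_ else d
  }, integer(1)), nx + 1L, ny + 1L, dimnames = list(0:nx, 0:ny))
  structure(list(C = C, tags = tags, mode = mode, scheme = scheme,
                 x = assembly$x, y = assembly$y, xc = assembly$xc, yc = assembly$yc,
                 nx = nx, ny = ny, w = w,
                 sd = assembly$sd, p = assembly$p, floor = assembly$floor,
                 affine = assembly$affine, engine = "mesh"),
            class = "dp_matrix")
}

#' @export
print.dp_matrix <- function(x, ...) {
  cat(sprintf("DP matrix (%s, %s engine): %d x %d, corner score %s\n",
              toupper(x$mode), x$engine, x$nx, x$ny,
              format(x$C[x$nx + 1L, x$ny + 1L])))
  invisible(x)
}

# wrap an oracle run in the same dp_matrix container (reference engine)
.reference_dp_matrix <- function(x, y, scheme, mode) {
  xc <- .chars(x); yc <- .chars(y)
  affine <- !is.null(scheme$affine) && mode != "lcs"
  if (affine) {
    o <- oracle_affine_tagged(x, y, scheme)
    C <- o$value
    dimnames(C) <- list(0:length(xc), 0:length(yc))
    tags <- o$tag
  } else {
    C <- oracle_dp(x, y, scheme, mode)$matrix
    tags <- NULL
  }
  sd <- if (mode == "lcs") outer(xc, yc, `==`) * 1L
        else if (length(xc) && length(yc))
          outer(xc, yc, function(a, b) scheme$matrix[cbind(a, b)])
        else matrix(0L, 1L, 1L)
  structure(list(C = C, tags = tags, mode = mode, scheme = scheme,
                 x = paste(xc, collapse = ""), y = paste(yc, collapse = ""),
                 xc = xc, yc = yc, nx = length(xc), ny = length(yc),
                 w = NA_integer_, sd = sd,
                 p = if (mode == "lcs") 0L else -scheme$gap,
                 floor = if (mode == "sw") scheme$beta else NULL,
                 affine = affine, engine = "reference"),
            class = "dp_matrix")
}

# ---- back-tracking ------------------------------------------------------

# argmax of a vector by the flag-bit subroutine: f(i,j) = a_i > a_j, column j
# holds the max iff ORing its flag column gives 0; smallest such index wins
.flag_argmax <- function(a) {
  f <- outer(a, a, `>`)
  ok <- colSums(f) == 0
  which(ok)[1L]
}

#' Locate the maximum cell of a DP matrix
#'
#' The staged constant-time procedure on the n x n x n mesh cube: the matrix
#' rows are fanned out to the 2D slices of the third dimension, each slice
#' finds the column of its row maximum with the flag-bit max-of-n subroutine
#' (set `f(i,j) = 1` iff `a_i > a_j`; a column whose ORed flags are 0 holds
#' the max), the winning column indices return to the first slice, and a
#' final max over the per-row maxima fixes the row.  Ties resolve to the
#' lexicographically smallest `(i, j)`.
#'
#' @param m a `dp_matrix` or a plain numeric matrix.
#' @return 0-based `c(i, j)` of the maximum cell.
#' @export
find_max_location <- function(m) {
  C <- if (inherits(m, "dp_matrix")) m$C else m
  C[is.na(C)] <- -Inf
  # stage 2-4: each slice k finds the column r_k of the max in row k
  r_k <- apply(C, 1L, .flag_argmax)
  # stage 5-6: the first slice takes the max over the per-row maxima
  vals <- C[cbind(seq_len(nrow(C)), r_k)]
  k <- .flag_argmax(vals)
  c(i = k - 1L, j = r_k[k] - 1L)
}

#' Trace back the optimal alignment path
#'
#' Starting from the end cell (`c[n,n]` for global alignment, the maximum
#' cell for local alignment), each cell fuses its port toward the neighbor
#' whose penalized contribution achieved the cell's value, and the alignment
#' is the ordered list of cells the back signal travels through.  Equal
#' contributions are broken deterministically (diagonal, then up, then left)
#' or, with `tie = "random"`, by a seeded random choice among the maximal
#' ports.  Local alignment stops at the first cell holding the floor value.
#'
#' @param m a `dp_matrix` from [run_dp()] or the reference engine.
#' @param end optional 0-based `c(i, j)` end cell; defaults to `c(n, n)` for
#'   NW/LCS and to [find_max_location()] for SW.
#' @param tie `"deterministic"` or `"random"`.
#' @param seed seed for `tie = "random"`.
#' @return an object of class `rmesh_alignment`: gapped `x_aln`/`y_aln`,
#'   `score`, the 0-based `path` matrix, `end` and `start` cells.
#' @export
dp_traceback <- function(m, end = NULL, tie = c("deterministic", "random"), seed = NULL) {
  tie <- match.arg(tie)
  stopifnot(inherits(m, "dp_matrix"))
  C <- m$C
  val <- function(i, j) {  # 0-based access; underflow reads as -Inf
    v <- C[i + 1L, j + 1L]
    if (is.na(v)) -Inf else v
  }
  if (is.null(end)) {
    end <- if (m$mode == "sw") find_max_location(m) else c(i = m$nx, j = m$ny)
  }
  if (tie == "random" && !is.null(seed)) set.seed(seed)
  floor <- if (m$mode == "sw") (if (is.null(m$floor)) 0 else m$floor) else NULL
  i <- end[[1L]]; j <- end[[2L]]
  path <- list(c(i, j))
  steps <- character(0)
  repeat {
    if (m$mode == "sw" && val(i, j) <= floor) break
    if (i == 0L && j == 0L) break
    if (i > 0L && j > 0L) {
      here <- val(i, j)
      if (m$mode == "lcs") {
        match <- m$sd[i, j] == 1L
        cand <- c(diag = if (match) val(i - 1L, j - 1L) + 1 else -Inf,
                  up   = if (!match) val(i - 1L, j) else -Inf,
                  left = if (!match) val(i, j - 1L) else -Inf)
      } else if (m$affine) {
        am <- function(v, t) {
          o <- m$scheme$affine$open; e <- m$scheme$affine$extend
          if (t == 1L) max(v - o, v - e) else v - o
        }
        cand <- c(diag = val(i - 1L, j - 1L) + m$sd[i, j],
                  up   = am(val(i - 1L, j), m$tags[i, j + 1L]),
                  left = am(val(i, j - 1L), m$tags[i + 1L, j]))
      } else {
        cand <- c(diag = val(i - 1L, j - 1L) + m$sd[i, j],
                  up   = val(i - 1L, j) - m$p,
                  left = val(i, j - 1L) - m$p)
      }
      hit <- names(cand)[cand == here]
      if (!length(hit)) {
        if (m$mode == "sw" && here == floor) break
        stop("dp_traceback: inconsistent matrix (no candidate reproduces the cell value)")
      }
      mv <- if (tie == "random" && length(hit) > 1L) sample(hit, 1L) else hit[1L]
    } else if (i > 0L) {
      mv <- "up"
    } else {
      mv <- "left"
    }
    if (mv == "diag") { i <- i - 1L; j <- j - 1L }
    else if (mv == "up") i <- i - 1L
    else j <- j - 1L
    steps <- c(mv, steps)
    path <- c(list(c(i, j)), path)
  }
  start <- c(i = i, j = j)
  xa <- character(0); ya <- character(0)
  ii <- i; jj <- j
  for (s in steps) {
    if (s == "diag") { ii <- ii + 1L; jj <- jj + 1L; xa <- c(xa, m$xc[ii]); ya <- c(ya, m$yc[jj]) }
    else if (s == "up") { ii <- ii + 1L; xa <- c(xa, m$xc[ii]); ya <- c(ya, "-") }
    else { jj <- jj + 1L; xa <- c(xa, "-"); ya <- c(ya, m$yc[jj]) }
  }
  structure(list(x_aln = paste(xa, collapse = ""), y_aln = paste(ya, collapse = ""),
                 score = C[end[[1L]] + 1L, end[[2L]] + 1L],
                 path = do.call(rbind, path), end = c(i = end[[1L]], j = end[[2L]]),
                 start = start, mode = m$mode),
            class = "rmesh_alignment")
}

#' @export
print.rmesh_alignment <- function(x, ...) {
  cat(sprintf("pairwise %s alignment, score %s\n", toupper(x$mode), format(x$score)))
  cat(" ", x$x_aln, "\n ", x$y_aln, "\n", sep = "")
  invisible(x)
}

#' Align two sequences on the simulated r-mesh
#'
#' Convenience wrapper: scales the scheme's substitution scores up to
#' non-negative values if needed, builds and runs the DP mesh (or the
#' sequential reference recurrence), and traces back the alignment.
#'
#' @param x,y sequences.
#' @param scheme a [scoring_scheme()].
#' @param mode `"nw"`, `"sw"` or `"lcs"`.
#' @param engine `"mesh"` (simulated r-mesh) or `"reference"` (sequential
#'   recurrence; the default for large inputs).
#' @param tie,seed traceback tie policy, see [dp_traceback()].
#' @return an `rmesh_alignment`; the DP matrix is attached as
#'   `attr(, "dp_matrix")` and the scheme actually used (after scaling) as
#'   `attr(, "scheme")`.
#' @examples
#' rmesh_align("GATTACA", "GCATGCA", scoring_scheme(match = 2, mismatch = 0, gap = -1))
#' @export
rmesh_align <- function(x, y, scheme = scoring_scheme(), mode = c("nw", "sw", "lcs"),
                        engine = c("mesh", "reference"),
                        tie = c("deterministic", "random"), seed = NULL) {
  mode <- match.arg(mode); engine <- match.arg(engine)
  if (mode != "lcs" && min(res_matrix(scheme)) < 0) scheme <- scheme_scale(scheme)
  m <- if (engine == "mesh") run_dp(build_dp_mesh(x, y, scheme, mode))
       else .reference_dp_matrix(x, y, scheme, mode)
  aln <- dp_traceback(m, tie = tie, seed = seed)
  attr(aln, "dp_matrix") <- m
  attr(aln, "scheme") <- scheme
  aln
}
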