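#' Scoring schemes for the alignment meshes
#'
#' A scheme bundles the residue alphabet, the substitution matrix (extended by
#' the gap symbol `-`), the linear gap score `g` (signed, usually negative:
#' the recurrence adds `g`, i.e. the mesh subtracts `|g|`), optional affine
#' gap costs (opening `o` and extension `g` as magnitudes, `o >= g`, so the
#' extra opening charge is `eps = o - g >= 0`), and the scale-up shift `beta`
#' already applied to the substitution scores.
#'
#' @param match,mismatch constant substitution scores used when `matrix` is
#'   not given.
#' @param gap signed linear gap score (must be `<= 0` for the mesh engine).
#' @param alphabet residue alphabet; defaults to DNA.
#' @param matrix optional T x T symmetric integer substitution matrix with
#'   residue dimnames (e.g. from [read_score_matrix()]).
#' @param gap_open,gap_extend optional affine gap cost magnitudes
#'   (`gap_open >= gap_extend >= 0`); when given, gap steps charge
#'   `gap_open` on opening and `gap_extend` on extension.
#' @param gap_gap score of a gap-gap pair in sum-of-pairs column scoring
#'   (not defined by the underlying model; defaults to 0).
#' @return an object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme(match = 2, mismatch = -1, gap = -2)
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(match = 1, mismatch = 0, gap = -1,
                           alphabet = c("A", "C", "G", "T"),
                           matrix = NULL, gap_open = NULL, gap_extend = NULL,
                           gap_gap = 0) {
  if (is.null(matrix)) {
    T <- length(alphabet)
    matrix <- base::matrix(as.numeric(mismatch), T, T,
                           dimnames = list(alphabet, alphabet))
    diag(matrix) <- match
  } else {
    stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
    alphabet <- rownames(matrix)
    if (!isTRUE(all.equal(matrix, t(matrix))))
      stop("scoring_scheme: substitution matrix must be symmetric")
  }
  if ("-" %in% alphabet)
    stop("scoring_scheme: the gap symbol is added automatically; do not include '-'")
  full <- rbind(cbind(matrix, "-" = gap), "-" = c(rep(gap, ncol(matrix)), gap_gap))
  affine <- NULL
  if (!is.null(gap_open)) {
    if (is.null(gap_extend)) gap_extend <- abs(gap)
    stopifnot(gap_open >= gap_extend, gap_extend >= 0)
    affine <- list(open = gap_open, extend = gap_extend, eps = gap_open - gap_extend)
  }
  structure(list(alphabet = alphabet, matrix = full, gap = gap,
                 affine = affine, beta = 0, gap_gap = gap_gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme over {%s}: gap %g%s, beta %g\n",
              paste(x$alphabet, collapse = ""), x$gap,
              if (!is.null(x$affine))
                sprintf(", affine open %g / extend %g", x$affine$open, x$affine$extend)
              else "", x$beta))
  print(x$matrix)
  invisible(x)
}

# residue-residue part of the full matrix
res_matrix <- function(scheme) {
  a <- scheme$alphabet
  scheme$matrix[a, a, drop = FALSE]
}

#' Scale a substitution matrix up to non-negative scores
#'
#' Adding a constant `beta` to every log-odds score is equivalent to
#' multiplying the underlying substitution probabilities by `a^beta` (with
#' `a` the log base), so it changes no score ordering within a column pair.
#' `beta` is chosen as the smallest shift making every score, including the
#' gap score, non-negative, which is what the unsigned 1UN mesh arithmetic
#' requires.
#'
#' @param matrix an integer substitution matrix.
#' @param g the signed gap score.
#' @return a list with the shifted `matrix`, shifted `gap`, and `beta`.
#' @examples
#' scale_up(matrix(c(2, -4, -4, 2), 2, 2, dimnames = list(c("A","B"), c("A","B"))), -2)$beta
#' @export
scale_up <- function(matrix, g) {
  beta <- max(0, -min(c(matrix, g)))
  list(matrix = matrix + beta, gap = g + beta, beta = beta)
}

# scale only the residue substitution scores of a scheme so the mesh's
# diagonal "+" units always add a non-negative value; the gap stays a
# subtraction through the "-" units (see the methods vignette).
scheme_scale <- function(scheme) {
  rm <- res_matrix(scheme)
  beta <- max(0, -min(rm))
  if (beta > 0) {
    a <- scheme$alphabet
    scheme$matrix[a, a] <- rm + beta
  }
  scheme$beta <- beta
  scheme
}

#' Recover the original-scheme score of an alignment
#'
#' After aligning with a scaled-up scheme, the score under the original
#' matrix is the prefix-sum over the alignment path of the original
#' substitution score for every diagonal (residue-residue) column and the
#' gap score for every gap column.
#'
#' @param result an alignment (class `rmesh_alignment`, or any list with
#'   `x_aln`/`y_aln` gapped strings).
#' @param matrix the original substitution matrix.
#' @param g the original signed gap score.
#' @return the original-scheme alignment score.
#' @export
rescore_original <- function(result, matrix, g) {
  xa <- strsplit(result$x_aln, "")[[1L]]
  ya <- strsplit(result$y_aln, "")[[1L]]
  stopifnot(length(xa) == length(ya))
  if (!length(xa)) return(0)
  isgap <- xa == "-" | ya == "-"
  step <- rep(g, length(xa))
  step[!isgap] <- matrix[cbind(xa[!isgap], ya[!isgap])]
  prefix <- cumsum(step)  # Theorem-1 prefix-sum, computed functionally
  prefix[length(prefix)]
}

#' Enumerate the residue pairs scored between two columns
#'
#' Merges the residues of columns `f` and `g` and lists every unordered pair
#' with its multiplicity; with `|f| + |g| = M` residues there are always
#' `choose(M, 2)` pairs in total.
#'
#' @param f,g character vectors of residue symbols (gap `-` allowed).
#' @return a list with `pairs` (data frame `a`, `b`, `count`, unordered with
#'   `a <= b`) and `total`.
#' @examples
#' sp_pairs(c("A","C","T"), c("G","T","T"))$total  # 15
#' @export
sp_pairs <- function(f, g) {
  stopifnot(length(f) >= 1L, length(g) >= 1L)
  merged <- c(f, g)
  cnt <- table(merged)
  syms <- names(cnt)
  out <- list()
  for (i in seq_along(syms)) {
    if (cnt[i] >= 2L)
      out[[length(out) + 1L]] <- data.frame(a = syms[i], b = syms[i],
                                            count = choose(cnt[[i]], 2))
    if (i < length(syms)) for (j in (i + 1L):length(syms))
      out[[length(out) + 1L]] <- data.frame(a = syms[i], b = syms[j],
                                            count = cnt[[i]] * cnt[[j]])
  }
  pairs <- do.call(rbind, out)
  pairs <- pairs[pairs$count > 0, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, total = choose(length(merged), 2))
}

#' Sum-of-pairs column score in counting form
#'
#' Computes the sum-of-pairs score of two alignment columns from the
#' per-symbol counts of their merged residue pool:
#' `sum_i C(n_i, 2) s(i,i) + sum_{i<j} n_i n_j s(i,j)`.
#' Because the number of symbol types is a constant, the cost is independent
#' of how many sequences contribute to the columns.  The merged pool includes
#' within-column pairs, matching the enumeration the brute-force definition
#' expands to.
#'
#' @param f,g character vectors of residue symbols (gap `-` allowed).
#' @param scheme a [scoring_scheme()] (its full matrix, including the gap
#'   symbol, supplies `s`), or a full substitution matrix with dimnames
#'   covering every symbol present.
#' @return the sum-of-pairs score.
#' @export
sum_of_pair <- function(f, g, scheme) {
  s <- if (inherits(scheme, "scoring_scheme")) scheme$matrix else scheme
  merged <- c(f, g)
  if (!all(merged %in% rownames(s)))
    stop("sum_of_pair: column symbol missing from the substitution matrix")
  cnt <- table(merged)
  syms <- names(cnt)
  total <- 0
  for (i in seq_along(syms)) {
    ni <- cnt[[i]]
    total <- total + choose(ni, 2) * s[syms[i], syms[i]]
    if (i < length(syms)) for (j in (i + 1L):length(syms))
      total <- total + ni * cnt[[j]] * s[syms[i], syms[j]]
  }
  total
}

#' Read a plain-text substitution matrix (NCBI format)
#'
#' Parses the standard PAM/BLOSUM text layout: `#` comment lines, a header
#' row of residue symbols, then one row per residue of integer scores.
#'
#' @param path file path.
#' @return a symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("read_score_matrix: no matrix content found")
  header <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
  if (any(vapply(vals, anyNA, logical(1))) ||
      any(lengths(vals) != length(header)))
    stop("read_score_matrix: malformed matrix row")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, header)
  # drop the stop/any column (*) present in NCBI protein matrices
  keep <- rownames(m) != "*"
  m <- m[keep, colnames(m) != "*", drop = FALSE]
  m
}
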