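#' FASTA input/output and synthetic sequence families
#'
#' @name io
NULL

#' Read sequences from a FASTA file
#'
#' Sequences are normalised to upper case; the gap symbol `-` is preserved so
#' aligned FASTA round-trips.
#'
#' @param path file path.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences (aligned or not) to a FASTA file
#'
#' @param seqs named character vector of sequences; an [aligned_group()] or
#'   `msa_result` may also be given.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "msa_result")) seqs <- seqs$alignment
  if (inherits(seqs, "aligned_group")) seqs <- group_strings(seqs)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# run a block with a private, seeded RNG stream, restoring the caller's
with_private_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic sequence family
#'
#' Draws one random ancestor and derives `m` descendants by independent
#' per-position substitutions (rate `mutation`, always to a different
#' symbol) and indels (rate `indel`, split evenly between a deletion of the
#' position and an insertion of a random symbol after it).  With a seed the
#' family regenerates bit-exactly.  Defaults emulate a small, closely
#' related DNA family of the size the mesh engine is meant for: 6 sequences
#' of length 12, 10% substitutions, 5% indels.
#'
#' @param m number of descendant sequences.
#' @param n ancestor length.
#' @param mutation per-position substitution probability in `[0, 1]`.
#' @param indel per-position indel probability in `[0, 1]`.
#' @param seed optional RNG seed (uses a private stream).
#' @param alphabet residue alphabet.
#' @return list with `seqs` (named character vector `seq1..seqm`) and
#'   `ancestor`.
#' @export
synth_family <- function(m = 6, n = 12, mutation = 0.1, indel = 0.05,
                         seed = NULL, alphabet = c("A", "C", "G", "T")) {
  stopifnot(m >= 1, n >= 1, mutation >= 0, mutation <= 1, indel >= 0, indel <= 1)
  with_private_seed(seed, {
    anc <- sample(alphabet, n, replace = TRUE)
    seqs <- character(m)
    for (s in seq_len(m)) {
      cur <- anc
      sub <- stats::runif(length(cur)) < mutation
      if (any(sub)) cur[sub] <- vapply(cur[sub], function(ch)
        sample(setdiff(alphabet, ch), 1L), character(1))
      out <- character(0)
      for (ch in cur) {
        u <- stats::runif(1)
        if (u < indel / 2) next                      # deletion
        out <- c(out, ch)
        if (u >= indel / 2 && u < indel)             # insertion after
          out <- c(out, sample(alphabet, 1L))
      }
      if (!length(out)) out <- sample(alphabet, 1L)  # keep sequences non-empty
      seqs[s] <- paste(out, collapse = "")
    }
    names(seqs) <- paste0("seq", seq_len(m))
    list(seqs = seqs, ancestor = paste(anc, collapse = ""))
  })
}
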