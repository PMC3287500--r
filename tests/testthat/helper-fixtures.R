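# shared fixtures: seeded random sequences, schemes and meshes

DNA <- c("A", "C", "G", "T")

random_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a random small integer scheme whose residue scores are already non-negative
# (i.e. scaled), with a non-positive gap -- what the mesh engine accepts
random_scaled_scheme <- function() {
  scoring_scheme(match = sample(1:5, 1), mismatch = sample(0:3, 1),
                 gap = -sample(0:3, 1))
}

# a random mesh on an nr x nc grid with uniformly chosen port partitions
random_mesh <- function(nr, nc) {
  pp <- port_partitions()
  keys <- as.vector(outer(0:(nr - 1L), 0:(nc - 1L), paste, sep = ","))
  parts <- lapply(sample(seq_along(pp), nr * nc, replace = TRUE), function(i) pp[[i]])
  names(parts) <- keys
  mesh_config(nr, nc, parts)
}

# per-bus OR oracle for broadcast results
broadcast_or_oracle <- function(mesh, drives) {
  buses <- oracle_flood_fill(mesh)
  vals <- stats::setNames(integer(length(unlist(buses))), unlist(buses))
  for (b in buses) {
    on <- any(names(drives) %in% b & drives != 0)
    vals[b] <- as.integer(on)
  }
  vals
}

# alignment path self-consistency: total charge along the traced path
# (steps into interior cells only; the zero boundary is free)
path_score <- function(m, aln) {
  p <- aln$path
  total <- 0
  for (t in seq_len(nrow(p) - 1L)) {
    from <- p[t, ]; to <- p[t + 1L, ]
    if (to[1L] == 0L || to[2L] == 0L) next  # still on the free boundary
    if (all(to - from == c(1L, 1L))) {
      total <- total + if (m$mode == "lcs") 1 else m$sd[to[1L], to[2L]]
    } else {
      total <- total - m$p
    }
  }
  total
}

# best group-alignment score by enumerating every monotone column path
enum_group_paths <- function(d, gA, gB) {
  nA <- nrow(d); nB <- ncol(d)
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    # the zero boundary makes any remaining leading gap run free
    best <- if (i == 0L || j == 0L) 0 else -Inf
    if (i > 0L && j > 0L) best <- max(best, rec(i - 1L, j - 1L) + d[i, j])
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gA[i])
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gB[j])
    best
  }
  rec(nA, nB)
}

# write a small NCBI-style plain-text matrix for parser tests
write_ncbi_matrix <- function(m, path) {
  lines <- c("# test matrix", paste(" ", paste(colnames(m), collapse = "  ")))
  for (r in rownames(m)) lines <- c(lines, paste(r, paste(m[r, ], collapse = "  ")))
  writeLines(lines, path)
  path
}
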