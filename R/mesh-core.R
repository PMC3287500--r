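#' The reconfigurable-mesh (r-mesh) substrate
#'
#' An r-mesh is a grid of processing units, each with four ports (N, S, E, W)
#' that can be fused into groups.  Fused port groups, together with the fixed
#' grid adjacency (E of `(r,c)` abuts W of `(r,c+1)`, S of `(r,c)` abuts N of
#' `(r+1,c)`), form buses: maximal connected sets of ports.  In one atomic
#' broadcasting step every bus carries the logical OR of all one-bit values
#' driven onto it, and every port on the bus reads that value.  All mesh
#' components in this package are evaluated through this single primitive.
#'
#' Coordinates are 0-based with row 0 at the top.  Grids may be sparse
#' (positions without a unit carry no ports and break adjacency), which is how
#' bit-sliced components keep their per-bit blocks electrically isolated.
#'
#' @name mesh_core
NULL

.PORTS <- c("N", "S", "E", "W")

#' Enumerate the 15 port partitions of a processing unit
#'
#' Returns every partition of the port set \{N, S, E, W\} into disjoint
#' non-empty fused groups (the Bell number of a 4-element set is 15).  The
#' five partitions containing a group of three or more ports are not allowed
#' in the Linear r-mesh (Lr-mesh) variant; see [is_lr_legal()].
#'
#' @return a list of 15 partitions, each a list of character vectors, in a
#'   stable canonical order (by number of groups, then lexicographically by
#'   the canonical string, e.g. `"NE|SW"`).
#' @examples
#' length(port_partitions())                  # 15
#' sum(!vapply(port_partitions(), is_lr_legal, logical(1)))  # 5
#' @export
port_partitions <- function() {
  parts <- .set_partitions(.PORTS)
  parts <- lapply(parts, .canon_partition)
  key <- vapply(parts, partition_key, character(1))
  ng <- lengths(parts)
  parts[order(ng, key)]
}

# all set partitions of a character vector (recursive refinement)
.set_partitions <- function(els) {
  if (length(els) == 1L) return(list(list(els)))
  first <- els[1L]
  rest <- .set_partitions(els[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

.canon_partition <- function(p) {
  p <- lapply(p, function(g) .PORTS[.PORTS %in% g])
  p[order(vapply(p, function(g) match(g[1L], .PORTS), numeric(1)))]
}

#' @rdname port_partitions
#' @param partition a partition as returned by [port_partitions()] (a list of
#'   character vectors over N, S, E, W), or its string shorthand `"NE|SW"`.
#' @return `partition_key` gives the canonical string form, e.g. `"NE|SW"`.
#' @export
partition_key <- function(partition) {
  if (is.character(partition)) return(partition_key(as_partition(partition)))
  paste(vapply(partition, paste, character(1), collapse = ""), collapse = "|")
}

#' @rdname port_partitions
#' @return `is_lr_legal` is `FALSE` for partitions with a fused group of three
#'   or more ports (illegal in the Lr-mesh model).
#' @export
is_lr_legal <- function(partition) {
  if (is.character(partition)) partition <- as_partition(partition)
  all(lengths(partition) < 3L)
}

#' @rdname port_partitions
#' @param x a partition given as a list of port groups or as shorthand like
#'   `"NE|SW"`.
#' @return `as_partition` returns the validated canonical partition list.
#' @export
as_partition <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- strsplit(strsplit(x, "|", fixed = TRUE)[[1L]], "")
  stopifnot(is.list(x))
  ports <- sort(unlist(x))
  if (!identical(ports, sort(.PORTS)))
    stop("as_partition: every port N,S,E,W must appear in exactly one group")
  .canon_partition(x)
}

#' Build a mesh configuration
#'
#' @param nrow,ncol grid dimensions.
#' @param partitions per-unit port partitions, named by `"r,c"` position keys
#'   (0-based): either a named character vector of shorthand strings like
#'   `"NE|SW"` (fast path for large components) or a named list of partition
#'   lists.  Positions not named carry no unit (sparse grid).
#' @param drives optional boundary/register inputs: a named numeric vector of
#'   bits with names `"r,c,P"` (`P` one of N, S, E, W) identifying the driven
#'   port.
#' @return an object of class `mesh_config`.
#' @examples
#' m <- mesh_config(1, 3, c("0,0" = "EW|N|S", "0,1" = "EW|N|S", "0,2" = "EW|N|S"))
#' length(bus_list(resolve_buses(m)))
#' @export
mesh_config <- function(nrow, ncol, partitions, drives = NULL) {
  stopifnot(nrow >= 1L, ncol >= 1L, length(partitions) >= 1L)
  keys <- names(partitions)
  if (is.null(keys) || any(keys == ""))
    stop("mesh_config: partitions must be named by 'r,c' position keys")
  if (anyDuplicated(keys)) stop("mesh_config: duplicate unit positions")
  if (is.list(partitions)) {
    part_str <- vapply(partitions, function(p) partition_key(as_partition(p)),
                       character(1))
  } else {
    part_str <- as.character(partitions)
    ups <- unique(part_str)
    canon <- vapply(ups, function(s) partition_key(as_partition(s)), character(1))
    part_str <- unname(canon[match(part_str, ups)])
  }
  pos <- matrix(as.integer(unlist(strsplit(keys, ",", fixed = TRUE))),
                ncol = 2L, byrow = TRUE)
  if (any(is.na(pos)) || any(pos[, 1L] < 0L) || any(pos[, 1L] >= nrow) ||
      any(pos[, 2L] < 0L) || any(pos[, 2L] >= ncol))
    stop("mesh_config: unit position outside grid dimensions")
  structure(list(dims = c(nrow, ncol), keys = keys, part_str = part_str,
                 pos = pos, drives = drives),
            class = "mesh_config")
}

#' @rdname mesh_config
#' @param mesh a `mesh_config`.
#' @return `mesh_units` returns the per-unit partitions as a named list of
#'   partition lists.
#' @export
mesh_units <- function(mesh) {
  stats::setNames(lapply(mesh$part_str, as_partition), mesh$keys)
}

#' Number of processing units
#'
#' Counts the simulated processing units of a mesh, component or assembly,
#' used for resource-accounting logs.
#'
#' @param x a `mesh_config`, `rmesh_component` or other mesh object.
#' @param ... passed to methods.
#' @export
pu_count <- function(x, ...) UseMethod("pu_count")

#' @export
pu_count.mesh_config <- function(x, ...) length(x$keys)

#' @export
pu_count.default <- function(x, ...) stop("pu_count: unsupported object")

# local port index for unit k (1-based) and port number p (1..4)
.loc <- function(k, p) (k - 1L) * 4L + p

# local port indices for "r,c,P" keys
port_index <- function(mesh, keys) {
  parts <- strsplit(keys, ",", fixed = TRUE)
  rc <- vapply(parts, function(p) paste0(p[1L], ",", p[2L]), character(1))
  pn <- vapply(parts, function(p) match(p[3L], .PORTS), numeric(1))
  k <- match(rc, mesh$keys)
  if (anyNA(k) || anyNA(pn)) stop("port_index: unknown port key")
  .loc(k, as.integer(pn))
}

#' Resolve the buses of a mesh
#'
#' Computes the connected components of the port graph whose edges are the
#' intra-unit fusions plus the inter-unit port adjacencies.  Bus ids are
#' deterministic (numbered by the smallest port they contain).  The bus
#' structure depends only on the configuration, not on the driven values, so
#' a resolved network is reused across broadcasts.
#'
#' @param mesh a [mesh_config()].
#' @return an object of class `bus_network` with elements `bus` (bus id per
#'   present port, in unit-major N,S,E,W order), `nbus`, and `keys` (the
#'   `"r,c,P"` label per port); [bus_list()] expands the buses as port-key
#'   sets.
#' @export
resolve_buses <- function(mesh) {
  n_unit <- length(mesh$keys)
  nport <- 4L * n_unit
  # intra-unit fusion edges, vectorized over units sharing a partition
  ea <- integer(0); eb <- integer(0)
  for (ps in unique(mesh$part_str)) {
    ks <- which(mesh$part_str == ps)
    for (g in as_partition(ps)) {
      if (length(g) > 1L) {
        pi <- match(g, .PORTS)
        for (t in 2:length(pi)) {
          ea <- c(ea, .loc(ks, pi[1L]))
          eb <- c(eb, .loc(ks, pi[t]))
        }
      }
    }
  }
  # adjacency edges between present units
  r <- mesh$pos[, 1L]; c <- mesh$pos[, 2L]
  east <- match(paste0(r, ",", c + 1L), mesh$keys)
  has <- which(!is.na(east))
  ea <- c(ea, .loc(has, 3L)); eb <- c(eb, .loc(east[has], 4L))
  south <- match(paste0(r + 1L, ",", c), mesh$keys)
  has <- which(!is.na(south))
  ea <- c(ea, .loc(has, 2L)); eb <- c(eb, .loc(south[has], 1L))
  memb <- if (length(ea)) {
    g <- igraph::graph_from_edgelist(cbind(ea, eb), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nport - igraph::vcount(g)))
    igraph::components(g)$membership
  } else seq_len(nport)
  # deterministic ids: number buses by their smallest port
  first <- match(unique(memb[order(seq_len(nport))]), memb)
  bus <- match(memb, memb[sort(first)])
  keys <- paste0(rep(r, each = 4L), ",", rep(c, each = 4L),
                 ",", rep(.PORTS, n_unit))
  structure(list(bus = bus, nbus = max(bus), keys = keys),
            class = "bus_network")
}

#' @rdname resolve_buses
#' @param net a `bus_network`.
#' @return `bus_list` returns the buses as a list of sorted `"r,c,P"` port
#'   key vectors, ordered by their first key.
#' @export
bus_list <- function(net) {
  buses <- split(net$keys, net$bus)
  buses <- lapply(buses, sort)
  names(buses) <- NULL
  buses[order(vapply(buses, `[`, character(1), 1L))]
}

#' @export
print.bus_network <- function(x, ...) {
  cat(sprintf("bus network: %d ports on %d buses\n", length(x$bus), x$nbus))
  invisible(x)
}

# hot path: drive bits at local port indices, read at local port indices;
# every bus reads the OR of its drivers
.broadcast_read <- function(net, in_idx, bits, out_idx) {
  busval <- integer(net$nbus)
  hot <- in_idx[bits != 0]
  if (length(hot)) busval[net$bus[hot]] <- 1L
  busval[net$bus[out_idx]]
}

#' One atomic broadcasting step
#'
#' Drives the configured input bits onto their ports and reads every port:
#' each bus carries the logical OR of all values driven onto it (the
#' common-collector electrical-bus rule), undriven buses read 0.  The result
#' is independent of evaluation order, deterministic, and idempotent.
#'
#' @param mesh a [mesh_config()] whose `drives` carry the boundary inputs, or
#'   pass `drives` explicitly.
#' @param drives named bit vector (`"r,c,P"` names) overriding `mesh$drives`.
#' @param net optionally a pre-resolved [resolve_buses()] network.
#' @return named integer vector of port values, one entry per present port,
#'   named by `"r,c,P"`.
#' @export
mesh_broadcast <- function(mesh, drives = NULL, net = NULL) {
  if (is.null(net)) net <- resolve_buses(mesh)
  if (is.null(drives)) drives <- mesh$drives
  in_idx <- integer(0); bits <- integer(0)
  if (!is.null(drives) && length(drives)) {
    in_idx <- match(names(drives), net$keys)
    if (anyNA(in_idx)) stop("mesh_broadcast: drive on a port that is not in the mesh")
    bits <- as.integer(drives != 0)
  }
  v <- .broadcast_read(net, in_idx, bits, seq_along(net$bus))
  names(v) <- net$keys
  v
}
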