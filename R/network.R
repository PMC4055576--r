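# Network construction, generators, multiplex layering and edge-list I/O.

canonicalEdges <- function(edges) {
  if (nrow(edges) == 0L) return(matrix(integer(), 0L, 2L))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

newNetwork <- function(N, edges, origIds = seq_len(N) - 1L, warnDisconnected = TRUE) {
  N <- as.integer(N)
  edges <- canonicalEdges(matrix(as.integer(edges), ncol = 2L))
  nbr <- rep(list(integer()), N)
  if (nrow(edges)) {
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    nbr <- unname(split(both[, 2], factor(both[, 1], levels = seq_len(N))))
    nbr <- lapply(nbr, sort)
    A <- Matrix::sparseMatrix(i = both[, 1], j = both[, 2], x = 1,
                              dims = c(N, N))
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(N, N))
  }
  conn <- isConnectedGraph(N, edges)
  if (!conn && warnDisconnected)
    warning("network is not connected; dynamics are well defined per component",
            call. = FALSE)
  new("ContagionNetwork", N = N, edges = edges, adjacency = A,
      neighbors = nbr, origIds = as.integer(origIds), connected = conn)
}

isConnectedGraph <- function(N, edges) {
  if (N == 1L) return(TRUE)
  if (nrow(edges) == 0L) return(FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < N) g <- igraph::add_vertices(g, N - igraph::vcount(g))
  igraph::is_connected(g)
}

#' Number of nodes
#' @param network a \linkS4class{ContagionNetwork} or
#'   \linkS4class{MultiplexContagionNetwork}.
#' @return integer node count.
#' @export
numNodes <- function(network) network@N

#' Edge matrix of a network
#' @param network a \linkS4class{ContagionNetwork}.
#' @return two-column integer matrix of internal (1-based) node pairs.
#' @export
networkEdges <- function(network) network@edges

#' Node degrees
#' @param network a \linkS4class{ContagionNetwork}.
#' @return integer vector of degrees k_i.
#' @export
nodeDegrees <- function(network) lengths(network@neighbors)

#' Neighbor list
#' @param network a \linkS4class{ContagionNetwork}.
#' @return list of integer vectors of neighbors per node.
#' @export
neighborList <- function(network) network@neighbors

#' Layers of a multiplex network
#' @param network a \linkS4class{MultiplexContagionNetwork}.
#' @return list of \linkS4class{ContagionNetwork} layers.
#' @export
networkLayers <- function(network) network@layers

#' Build a named graph
#'
#' Generators for the small canonical topologies used throughout:
#' \code{complete(n)} with n(n-1)/2 edges, \code{star(n)} with a degree-(n-1)
#' hub (node 1), \code{ring(n)} with n edges, and the periodic 2-D lattice
#' (torus) in which every node has degree 4 for dimensions of at least 3.
#'
#' @param kind one of \code{"complete"}, \code{"star"}, \code{"ring"},
#'   \code{"lattice2d_periodic"}.
#' @param n node count (complete/star/ring).
#' @param rows,cols lattice dimensions; both must be >= 3 (a smaller torus
#'   would wrap onto duplicate edges).
#' @return a \linkS4class{ContagionNetwork}.
#' @examples
#' makeGraph("complete", 6)
#' makeGraph("lattice2d_periodic", rows = 3, cols = 3)
#' @export
makeGraph <- function(kind = c("complete", "star", "ring", "lattice2d_periodic"),
                      n = NULL, rows = NULL, cols = NULL) {
  kind <- match.arg(kind)
  if (kind == "lattice2d_periodic") {
    if (is.null(rows) || is.null(cols))
      stop("lattice2d_periodic requires rows and cols")
    if (rows < 3L || cols < 3L)
      stop("periodic lattice requires rows >= 3 and cols >= 3 ",
           "(torus wrap-around would create duplicate edges)")
    g <- igraph::make_lattice(dimvector = c(rows, cols), periodic = TRUE)
  } else {
    if (is.null(n) || n < 1L) stop("size must be >= 1")
    g <- switch(kind,
      complete = igraph::make_full_graph(n),
      star = igraph::make_star(n, mode = "undirected", center = 1),
      ring = if (n <= 2L)
        igraph::make_full_graph(n) else igraph::make_ring(n))
  }
  E <- igraph::as_edgelist(g, names = FALSE)
  newNetwork(igraph::vcount(g), E, warnDisconnected = FALSE)
}

#' Combine layers into a multiplex network
#'
#' @param layers list of \linkS4class{ContagionNetwork} over the same node
#'   universe (identical N).
#' @return a \linkS4class{MultiplexContagionNetwork}.
#' @export
makeMultiplex <- function(layers) {
  if (!length(layers)) stop("need at least one layer")
  N <- layers[[1]]@N
  new("MultiplexContagionNetwork", N = N, layers = layers,
      origIds = layers[[1]]@origIds)
}

parseEdgeTokens <- function(lines) {
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  n <- lengths(toks)
  if (any(n < 2L | n > 3L))
    stop("edge list parse error at line ", keep[which(n < 2L | n > 3L)[1]],
         ": expected 2 or 3 fields")
  vals <- suppressWarnings(lapply(toks, as.integer))
  bad <- vapply(vals, function(v) anyNA(v), TRUE) |
    vapply(seq_along(toks), function(i)
      any(vals[[i]] != suppressWarnings(as.numeric(toks[[i]]))), TRUE)
  if (any(bad))
    stop("edge list parse error at line ", keep[which(bad)[1]],
         ": non-integer token")
  list(vals = vals, lineNo = keep)
}

#' Load a network from a plain-text edge list
#'
#' Reads whitespace- or comma-delimited integer pairs, one edge per line, with
#' an optional third integer column giving a layer index (producing a
#' \linkS4class{MultiplexContagionNetwork}).  \code{#} comments are ignored.
#' Duplicate and reversed edges are deduplicated; arbitrary integer node
#' identifiers are compacted to internal indices with the original ids
#' retained in the returned object.  Self-loops and non-integer tokens are
#' rejected with the offending line number.
#'
#' @param path file to read.
#' @return a \linkS4class{ContagionNetwork}, or a
#'   \linkS4class{MultiplexContagionNetwork} when a layer column is present.
#' @export
loadEdgeList <- function(path) {
  p <- parseEdgeTokens(readLines(path))
  vals <- p$vals
  n <- lengths(vals)
  if (length(unique(n)) > 1L)
    stop("edge list parse error at line ",
         p$lineNo[which(n != n[1])[1]],
         ": inconsistent number of fields")
  uv <- t(vapply(vals, function(v) v[1:2], integer(2)))
  self <- uv[, 1] == uv[, 2]
  if (any(self))
    stop("self-loop rejected at line ", p$lineNo[which(self)[1]])
  ids <- sort(unique(as.vector(uv)))
  iu <- match(uv[, 1], ids)
  iv <- match(uv[, 2], ids)
  N <- length(ids)
  if (n[1] == 3L) {
    lay <- vapply(vals, function(v) v[3], integer(1))
    layIds <- sort(unique(lay))
    layers <- lapply(layIds, function(a) {
      sel <- lay == a
      newNetwork(N, cbind(iu[sel], iv[sel]), origIds = ids,
                 warnDisconnected = FALSE)
    })
    makeMultiplex(layers)
  } else {
    newNetwork(N, cbind(iu, iv), origIds = ids)
  }
}

#' Write a network as a plain-text edge list
#'
#' Emits the canonical form (sorted pairs, one per line, original node
#' identifiers) so that \code{loadEdgeList(writeEdgeList(x))} round-trips
#' bit-exactly.  Multiplex networks gain a third layer column.
#'
#' @param network a \linkS4class{ContagionNetwork} or
#'   \linkS4class{MultiplexContagionNetwork}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  if (is(network, "MultiplexContagionNetwork")) {
    rows <- do.call(rbind, lapply(seq_along(network@layers), function(a) {
      E <- network@layers[[a]]@edges
      if (!nrow(E)) return(NULL)
      cbind(network@origIds[E[, 1]], network@origIds[E[, 2]], a)
    }))
    lines <- if (is.null(rows)) character(0) else
      apply(rows, 1, paste, collapse = " ")
  } else {
    E <- network@edges
    lines <- if (!nrow(E)) character(0) else
      apply(cbind(network@origIds[E[, 1]], network@origIds[E[, 2]]),
            1, paste, collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}
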