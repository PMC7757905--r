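#' Construct a hypergraph
#'
#' A hypergraph is a set of nodes plus an ordered list of hyperedges, each a
#' set of at least two distinct nodes. Here hyperedges typically represent
#' motif instances (e.g. triangles, or the participants of one metabolic
#' reaction), so the structure doubles as a "motif hypergraph". Duplicate
#' hyperedges are kept as distinct entries (a multi-hypergraph): motif
#' enumeration on directed graphs can legitimately produce multiplicity, and
#' the flow diffusion treats each instance's capacity separately.
#'
#' External node labels (integers or strings) are mapped to dense internal
#' indices; all exported functions accept and return external labels.
#'
#' @param edges list of vectors of node labels, one hyperedge per element;
#'   each hyperedge must contain >= 2 distinct labels.
#' @param nodes optional vector of additional (possibly isolated) node labels.
#' @return An object of class `hypergraph` with fields `labels` (external
#'   labels in internal-index order), `edges` (list of sorted internal index
#'   vectors, in input order), `incidence` (per-node list of incident edge
#'   indices), `eta` (number of hyperedges containing each node), `d` (motif
#'   degree of each node) and `k_uniform` (the common hyperedge size, or NA).
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(2, 3, 4)))
#' motif_degree(H, 2)
#' @export
hypergraph <- function(edges, nodes = NULL) {
  stopifnot(is.list(edges))
  labs <- unique(c(unlist(lapply(edges, as.character), use.names = FALSE),
                   as.character(nodes)))
  # numeric-looking label sets sort numerically, otherwise lexicographically
  if (length(labs) && !anyNA(suppressWarnings(as.numeric(labs)))) {
    labs <- labs[order(as.numeric(labs))]
  } else {
    labs <- sort(labs)
  }
  idx <- seq_along(labs)
  names(idx) <- labs
  eint <- vector("list", length(edges))
  for (i in seq_along(edges)) {
    e <- as.character(edges[[i]])
    if (anyDuplicated(e)) {
      stop("hyperedge ", i, " contains a repeated node: {",
           paste(e, collapse = ", "), "}")
    }
    if (length(e) < 2) {
      stop("hyperedge ", i, " has fewer than 2 nodes")
    }
    eint[[i]] <- sort(unname(idx[e]))
  }
  new_hypergraph(labs, eint)
}

# internal constructor from validated parts: external labels + internal-index edges
new_hypergraph <- function(labels, edges_int) {
  n <- length(labels)
  incidence <- vector("list", n)
  if (n > 0L) incidence[] <- list(integer(0))
  sizes <- lengths(edges_int)
  if (length(edges_int)) {
    flat <- unlist(edges_int, use.names = FALSE)
    eidx <- rep.int(seq_along(edges_int), sizes)
    incidence <- unname(split(eidx, factor(flat, levels = seq_len(n))))
  }
  eta <- lengths(incidence)
  d <- vapply(incidence, function(ix) sum(sizes[ix] - 1L), integer(1))
  ku <- if (length(sizes) && length(unique(sizes)) == 1L) sizes[[1L]] else NA_integer_
  structure(list(labels = labels, edges = edges_int, incidence = incidence,
                 eta = eta, d = d, k_uniform = ku),
            class = "hypergraph")
}

#' @exportS3Method base::print
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph: %d nodes, %d hyperedges%s\n",
              length(x$labels), length(x$edges),
              if (!is.na(x$k_uniform)) sprintf(" (%d-uniform)", x$k_uniform) else ""))
  invisible(x)
}

#' Number of nodes / hyperedges
#' @param H a [hypergraph()]
#' @return integer count
#' @export
hg_n_nodes <- function(H) length(H$labels)

#' @rdname hg_n_nodes
#' @export
hg_n_edges <- function(H) length(H$edges)

#' Node labels of a hypergraph
#' @param H a [hypergraph()]
#' @return character vector of external labels
#' @export
hg_nodes <- function(H) H$labels

#' Hyperedges with external labels
#' @param H a [hypergraph()]
#' @return list of character vectors
#' @export
hg_edges <- function(H) lapply(H$edges, function(e) H$labels[e])

# map external labels to internal indices, erroring on unknown nodes
hg_index <- function(H, v) {
  i <- match(as.character(v), H$labels)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(as.character(v)[is.na(i)], collapse = ", "))
  }
  i
}

#' Motif degree of nodes
#'
#' The motif degree d_M(v) of a node is the number of motif end points it
#' accounts for: for a k-uniform hypergraph d_M(v) = (k-1) * eta(v) where
#' eta(v) is the number of hyperedges containing v; for variable hyperedge
#' sizes the per-edge-additive extension d_M(v) = sum over edges e containing
#' v of (|e|-1) is used, which reduces to the former when uniform.
#'
#' @param H a [hypergraph()]
#' @param v node label(s); default all nodes
#' @return named integer vector of motif degrees
#' @export
motif_degree <- function(H, v = NULL) {
  if (is.null(v)) {
    stats::setNames(H$d, H$labels)
  } else {
    i <- hg_index(H, v)
    stats::setNames(H$d[i], H$labels[i])
  }
}

#' Number of hyperedges containing each node
#' @inheritParams motif_degree
#' @return named integer vector
#' @export
hyperedge_count <- function(H, v = NULL) {
  if (is.null(v)) {
    stats::setNames(H$eta, H$labels)
  } else {
    i <- hg_index(H, v)
    stats::setNames(H$eta[i], H$labels[i])
  }
}

#' Motif volume of a node set
#'
#' vol_M(S) counts motif-instance end points in S, i.e. the sum of eta(v)
#' over members. With `scaled = TRUE` the "hatted" volume sum of d_M(v) is
#' returned instead, which equals (k-1) * vol_M(S) for k-uniform hypergraphs.
#'
#' @param H a [hypergraph()]
#' @param S vector of node labels (a candidate cluster); may be empty
#' @param scaled return the motif-degree-weighted volume instead
#' @return non-negative integer
#' @export
motif_volume <- function(H, S, scaled = FALSE) {
  if (length(S) == 0L) return(0L)
  i <- hg_index(H, S)
  if (anyDuplicated(i)) i <- unique(i)
  if (scaled) sum(H$d[i]) else sum(H$eta[i])
}

#' Convert an undirected graph to its 2-uniform edge hypergraph
#'
#' Each graph edge becomes one 2-node hyperedge, in igraph edge order. Motif
#' degrees of the result equal graph degrees, so diffusion on it reproduces
#' the edge-based CRD process exactly.
#'
#' @param G an undirected [igraph::igraph] graph
#' @return a [hypergraph()]
#' @export
as_edge_hypergraph <- function(G) {
  stopifnot(igraph::is_igraph(G))
  if (igraph::is_directed(G)) stop("G must be undirected")
  el <- igraph::as_edgelist(G, names = TRUE)
  labs <- graph_labels(G)
  hypergraph(lapply(seq_len(nrow(el)), function(i) el[i, ]), nodes = labs)
}

# external labels of an igraph graph: name attribute when present, else 1..n
graph_labels <- function(G) {
  if ("name" %in% igraph::vertex_attr_names(G)) {
    as.character(igraph::V(G)$name)
  } else {
    as.character(seq_len(igraph::vcount(G)))
  }
}
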