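#' Built-in 3-node motif specifications
#'
#' The undirected `triangle` and the three directed triads used for clustering
#' directed interaction networks: `M1` (a triangle in any direction: every one
#' of the three node pairs joined by at least one arc), `M2` (a directed
#' 3-cycle) and `M3` (a feed-forward loop a->b, a->c, b->c).
#'
#' @param name one of `"triangle"`, `"M1"`, `"M2"`, `"M3"`
#' @return an object of class `motif_spec` with fields `name`, `size`,
#'   `directed`
#' @export
motif_spec <- function(name = c("triangle", "M1", "M2", "M3")) {
  name <- match.arg(name)
  structure(list(name = name, size = 3L, directed = name != "triangle"),
            class = "motif_spec")
}

#' @exportS3Method base::print
print.motif_spec <- function(x, ...) {
  cat(sprintf("motif '%s' (%d nodes, %s)\n", x$name, x$size,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Enumerate motif instances as a motif hypergraph
#'
#' Lists every unordered node triple of `G` realizing the motif pattern and
#' returns them as hyperedges on `G`'s full node set. Each triple is emitted
#' once per motif type regardless of how many arc orientations realize the
#' pattern on it, so hypergraph cuts count motif instances at the triple
#' level. Hyperedges are ordered lexicographically by sorted node triple for
#' deterministic downstream tie-breaking.
#'
#' @param G an [igraph::igraph] graph without self-loops; must be directed
#'   for M1/M2/M3 and undirected for the triangle
#' @param motif a [motif_spec()] or its name
#' @return a [hypergraph()] on all of `G`'s nodes (possibly with isolated
#'   nodes)
#' @export
enumerate_motifs <- function(G, motif = motif_spec("triangle")) {
  if (is.character(motif)) motif <- motif_spec(motif)
  stopifnot(igraph::is_igraph(G), inherits(motif, "motif_spec"))
  if (any(igraph::which_loop(G))) stop("G must have no self-loops")
  if (igraph::is_directed(G) != motif$directed) {
    stop("motif '", motif$name, "' requires a ",
         if (motif$directed) "directed" else "undirected", " graph")
  }
  labs <- graph_labels(G)
  if (motif$name == "triangle") {
    tri <- matrix(as.integer(igraph::triangles(G)), nrow = 3L)
  } else {
    # every directed triad's node set is a triangle of the undirected skeleton
    skel <- igraph::as_undirected(G, mode = "collapse")
    tri <- matrix(as.integer(igraph::triangles(skel)), nrow = 3L)
    if (ncol(tri)) {
      A <- igraph::as_adjacency_matrix(G, sparse = TRUE)
      A <- (A > 0) * 1
      keep <- vapply(seq_len(ncol(tri)), function(i) {
        triad_matches(A, tri[1, i], tri[2, i], tri[3, i], motif$name)
      }, logical(1))
      tri <- tri[, keep, drop = FALSE]
    }
  }
  if (ncol(tri)) {
    tri <- apply(tri, 2L, sort)
    tri <- tri[, order(tri[1, ], tri[2, ], tri[3, ]), drop = FALSE]
    edges <- lapply(seq_len(ncol(tri)), function(i) labs[tri[, i]])
  } else {
    edges <- list()
  }
  hypergraph(edges, nodes = labs)
}

# does the (skeleton-triangle) triple {a,b,c} realize the named directed triad?
triad_matches <- function(A, a, b, c, name) {
  switch(name,
    M1 = TRUE, # all three pairs connected by construction of the skeleton
    M2 = (A[a, b] & A[b, c] & A[c, a]) || (A[b, a] & A[c, b] & A[a, c]),
    M3 = {
      perms <- rbind(c(a, b, c), c(a, c, b), c(b, a, c),
                     c(b, c, a), c(c, a, b), c(c, b, a))
      any(vapply(seq_len(6L), function(i) {
        x <- perms[i, ]
        A[x[1], x[2]] && A[x[1], x[3]] && A[x[2], x[3]]
      }, logical(1)))
    },
    stop("unknown motif"))
}

#' Motif adjacency matrix as a weighted graph
#'
#' Builds the weighted undirected graph whose entry W_M(i, j) is the number
#' of hyperedges (motif instances) containing both i and j — the
#' clique-expansion weighting of the motif hypergraph. For 3-node motifs,
#' conductance on this graph equals motif conductance on the hypergraph.
#'
#' @param H a [hypergraph()]
#' @return a weighted undirected [igraph::igraph] graph on `H`'s nodes with
#'   integer `weight` edge attribute; pairs that co-occur in no hyperedge get
#'   no edge
#' @export
motif_adjacency <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  n <- hg_n_nodes(H)
  W <- motif_adjacency_matrix(H)
  G <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(G)$name <- H$labels
  G
}

# sparse symmetric co-occurrence count matrix (zero diagonal), internal indices
motif_adjacency_matrix <- function(H) {
  n <- hg_n_nodes(H)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (e in H$edges) {
    p <- utils::combn(e, 2L)
    pairs_i <- c(pairs_i, p[1, ])
    pairs_j <- c(pairs_j, p[2, ])
  }
  W <- Matrix::sparseMatrix(i = c(pairs_i, pairs_j), j = c(pairs_j, pairs_i),
                            x = 1, dims = c(n, n))
  methods::as(W, "CsparseMatrix")
}
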