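#' Conductance of a node set in a graph
#'
#' The conductance of S is |cut(S)| / min(vol(S), vol(V-S)): the number (or,
#' for weighted graphs, total weight) of edges with exactly one end point in
#' S, divided by the smaller side's (weighted-)degree volume. Low values
#' indicate a set that is well connected internally and sparsely connected to
#' the rest of the graph.
#'
#' @param G an undirected [igraph::igraph] graph, optionally with a `weight`
#'   edge attribute
#' @param S vector of node labels; must be a nonempty proper subset with
#'   positive min-side volume
#' @return conductance in `[0, Inf)` (finite; `<= 1` for unweighted graphs)
#' @export
conductance <- function(G, S) {
  stopifnot(igraph::is_igraph(G))
  if (igraph::is_directed(G)) stop("conductance is defined on undirected graphs")
  labs <- graph_labels(G)
  i <- match(as.character(S), labs)
  if (anyNA(i)) stop("unknown node(s) in S")
  i <- unique(i)
  deg <- igraph::strength(G, weights = igraph::E(G)$weight)
  in_S <- rep(FALSE, igraph::vcount(G))
  in_S[i] <- TRUE
  el <- igraph::as_edgelist(G, names = FALSE)
  w <- igraph::E(G)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  cut_w <- sum(w[in_S[el[, 1]] != in_S[el[, 2]]])
  mv <- min(sum(deg[in_S]), sum(deg[!in_S]))
  if (mv <= 0) {
    stop("conductance undefined: min-side volume is zero (S empty, S = V, ",
         "or all degree on one side)")
  }
  cut_w / mv
}

#' Motif cut of a node set
#'
#' The number of hyperedges (motif instances) with at least one end point in
#' S and at least one end point outside S.
#'
#' @param H a [hypergraph()]
#' @param S vector of node labels, a subset of `H`'s nodes (may be empty)
#' @return non-negative integer count
#' @export
motif_cut <- function(H, S) {
  stopifnot(inherits(H, "hypergraph"))
  if (length(S) == 0L) return(0L)
  i <- unique(hg_index(H, S))
  in_S <- rep(FALSE, hg_n_nodes(H))
  in_S[i] <- TRUE
  sizes <- lengths(H$edges)
  if (!length(sizes)) return(0L)
  k_in <- vapply(H$edges, function(e) sum(in_S[e]), integer(1))
  sum(k_in > 0L & k_in < sizes)
}

#' Motif conductance of a node set
#'
#' phi_M(S) = |cut_M(S)| / min(vol_M(S), vol_M(V-S)): motif instances
#' straddling the boundary of S over the smaller side's count of motif
#' end points (see [motif_cut()], [motif_volume()]). Undefined (an error)
#' when the smaller side carries no motif end points; sweep procedures skip
#' such sets rather than receiving a sentinel.
#'
#' @inheritParams motif_cut
#' @return motif conductance in `[0, 1]`
#' @export
motif_conductance <- function(H, S) {
  stopifnot(inherits(H, "hypergraph"))
  vS <- motif_volume(H, S)
  vT <- sum(H$eta) - vS
  mv <- min(vS, vT)
  if (mv <= 0) {
    stop("motif conductance undefined: min-side motif volume is zero")
  }
  motif_cut(H, S) / mv
}

#' Precision / recall / F1 of a detected cluster against ground truth
#'
#' @param found vector of node labels returned by an algorithm
#' @param truth vector of ground-truth node labels (nonempty)
#' @return a one-row [tibble::tibble] with columns `precision`, `recall`,
#'   `f1`; an empty `found` yields all zeros
#' @export
cluster_eval <- function(found, truth) {
  truth <- unique(as.character(truth))
  if (length(truth) == 0L) stop("truth must be nonempty")
  found <- unique(as.character(found))
  if (length(found) == 0L) {
    return(tibble::tibble(precision = 0, recall = 0, f1 = 0))
  }
  inter <- length(intersect(found, truth))
  p <- inter / length(found)
  r <- inter / length(truth)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(precision = p, recall = r, f1 = f1)
}
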