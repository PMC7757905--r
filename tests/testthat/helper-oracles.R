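# brute-force oracles and random generators shared across tests; the oracles
# deliberately use naive per-edge loops over external labels, independent of
# the package's incidence-indexed code paths

rand_hypergraph <- function(n, m, kmin = 2L, kmax = 4L) {
  edges <- lapply(seq_len(m), function(i) {
    k <- sample(kmin:kmax, 1L)
    sample.int(n, min(k, n))
  })
  hypergraph(edges, nodes = seq_len(n))
}

naive_motif_cut <- function(H, S) {
  S <- as.character(S)
  sum(vapply(hg_edges(H), function(e) any(e %in% S) && !all(e %in% S),
             logical(1)))
}

naive_motif_vol <- function(H, S) {
  S <- as.character(S)
  sum(vapply(hg_edges(H), function(e) sum(e %in% S), numeric(1)))
}

naive_phi <- function(H, S) {
  v1 <- naive_motif_vol(H, S)
  v2 <- naive_motif_vol(H, setdiff(hg_nodes(H), as.character(S)))
  if (min(v1, v2) <= 0) return(NA_real_)
  naive_motif_cut(H, S) / min(v1, v2)
}

rand_gnp <- function(n, p, directed = FALSE) {
  G <- igraph::sample_gnp(n, p, directed = directed)
  igraph::V(G)$name <- as.character(seq_len(n))
  G
}

brute_triangles <- function(G) {
  A <- as.matrix(igraph::as_adjacency_matrix(G))
  labs <- igraph::V(G)$name
  n <- nrow(A)
  if (n < 3L) return(list())
  tri <- utils::combn(n, 3L)
  keep <- A[cbind(tri[1, ], tri[2, ])] & A[cbind(tri[2, ], tri[3, ])] &
    A[cbind(tri[1, ], tri[3, ])]
  lapply(which(keep > 0), function(i) labs[tri[, i]])
}

# canonical form for comparing hyperedge lists as multisets of node sets
edge_multiset <- function(H) {
  sort(vapply(hg_edges(H), function(e) paste(sort(e), collapse = "|"),
              character(1)))
}

fig1_params <- function() crd_params(C = 2, h = 2, tau = 2, t = 5, alpha = 1)
std_params <- function() crd_params(C = 3, h = 3, tau = 2, t = 20, alpha = 1)

# all subsets of 1..n as a logical matrix (2^n rows)
subset_matrix <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  dimnames(m) <- NULL
  m
}
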