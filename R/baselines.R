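# ranked one-hop neighborhood of a seed: nodes co-occurring with the seed in
# >= 1 hyperedge, with shared-hyperedge counts
seed_neighborhood <- function(H, seed) {
  si <- hg_index(H, seed)
  eidx <- H$incidence[[si]]
  nb <- unlist(H$edges[eidx], use.names = FALSE)
  nb <- nb[nb != si]
  if (length(nb) == 0L) {
    return(list(si = si, nodes = integer(0), shared = integer(0)))
  }
  tab <- table(nb)
  list(si = si, nodes = as.integer(names(tab)), shared = as.integer(tab))
}

#' TopNeighbors baseline
#'
#' Orders the nodes in the one-hop hypergraph neighborhood of the seed by
#' the number of hyperedges they share with the seed (ties broken by
#' ascending node label) and returns the seed plus the top `k` neighbors
#' (all of them when fewer than `k` exist).
#'
#' @param H a [hypergraph()]
#' @param seed seed node label
#' @param k positive integer number of neighbors to keep
#' @return character vector of node labels (seed included)
#' @export
top_neighbors <- function(H, seed, k) {
  stopifnot(inherits(H, "hypergraph"), k >= 1)
  nb <- seed_neighborhood(H, seed)
  ord <- order(-nb$shared, nb$nodes)
  keep <- nb$nodes[ord][seq_len(min(k, length(nb$nodes)))]
  H$labels[sort(unique(c(nb$si, keep)))]
}

#' BestNeighbors baseline
#'
#' Like [top_neighbors()], but each neighbor `v` is ranked by the fraction
#' of the hyperedges containing `v` that also contain the seed, i.e.
#' shared-with-seed count divided by `v`'s hyperedge count.
#'
#' @inheritParams top_neighbors
#' @return character vector of node labels (seed included)
#' @export
best_neighbors <- function(H, seed, k) {
  stopifnot(inherits(H, "hypergraph"), k >= 1)
  nb <- seed_neighborhood(H, seed)
  score <- nb$shared / H$eta[nb$nodes]
  ord <- order(-score, nb$nodes)
  keep <- nb$nodes[ord][seq_len(min(k, length(nb$nodes)))]
  H$labels[sort(unique(c(nb$si, keep)))]
}
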