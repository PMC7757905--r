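#' The 9-reaction metabolic motif hypergraph
#'
#' A small fixture from a metabolic interaction network: ten metabolite
#' nodes and nine 3-node motif instances. Useful as a worked example for the
#' diffusion and as an exhaustively checkable test case (2^10 subsets).
#'
#' @return a 3-uniform [hypergraph()] with 10 nodes and 9 hyperedges
#' @examples
#' H <- metabolic_fixture()
#' motif_degree(H, 7)
#' @export
metabolic_fixture <- function() {
  hypergraph(list(
    c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 5, 10), c(2, 3, 4),
    c(1, 6, 7), c(1, 7, 8), c(5, 6, 7), c(6, 8, 9)))
}

#' Path-of-triangles localization family
#'
#' Builds the graph family used to study diffusion localization: `p`
#' triangle strips of `l` edge-sharing triangles each, every strip attached
#' by one triangle to a hub node, and the hub bridged by a single triangle
#' to a dense outside clique of `2 * l` nodes. The inside cluster `B` (hub
#' plus all strip nodes) contains `p * (l + 1)` triangles; a local diffusion
#' seeded at the hub should keep almost all of its mass inside `B` because
#' only one triangle crosses the bridge.
#'
#' @param p number of triangle strips, `>= 2`
#' @param l triangles per strip, `>= 1`
#' @return list with `graph` (undirected [igraph::igraph]), `B` (labels of
#'   the inside cluster), `hub` (the hub's label) and `bridge` (label of the
#'   outside attachment node)
#' @export
fig3_family <- function(p, l) {
  stopifnot(p >= 2, l >= 1)
  hub <- 1L
  nxt <- 2L
  from <- integer(0)
  to <- integer(0)
  B <- hub
  for (i in seq_len(p)) {
    z <- nxt:(nxt + l + 1L) # strip of l+2 nodes => l triangles
    nxt <- nxt + l + 2L
    a <- z[seq_len(l + 1L)]
    from <- c(from, a, z[seq_len(l)])
    to <- c(to, z[-1L], z[seq_len(l) + 2L])
    from <- c(from, hub, hub) # attachment triangle {hub, z1, z2}
    to <- c(to, z[1L], z[2L])
    B <- c(B, z)
  }
  w <- nxt:(nxt + 2L * l - 1L) # outside clique
  cl <- utils::combn(w, 2L)
  from <- c(from, cl[1, ], hub, hub) # bridge triangle {hub, w1, w2}
  to <- c(to, cl[2, ], w[1L], w[2L])
  G <- igraph::graph_from_edgelist(cbind(as.character(from), as.character(to)),
                                   directed = FALSE)
  list(graph = G, B = as.character(B), hub = as.character(hub),
       bridge = as.character(w[1L]))
}

#' Planted two-block (or multi-block) hypergraph specification
#'
#' @param block_sizes positive integer sizes of the ground-truth blocks
#' @param p_in probability of each within-block candidate hyperedge
#' @param p_out probability of each cross-block candidate hyperedge;
#'   must satisfy `0 <= p_out < p_in <= 1`
#' @param edge_size hyperedge size, `>= 2`
#' @param rng_seed integer seed; generation is a pure function of the spec
#' @param max_candidates cap on the enumerated candidate node sets; beyond
#'   it candidates are uniformly subsampled and the acceptance probabilities
#'   scaled to preserve the expected hyperedge counts
#' @return an object of class `planted_spec`
#' @export
planted_spec <- function(block_sizes, p_in, p_out, edge_size = 3L,
                         rng_seed = 1L, max_candidates = 200000L) {
  stopifnot(all(block_sizes >= 1), edge_size >= 2,
            p_out >= 0, p_out < p_in, p_in <= 1)
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, edge_size = as.integer(edge_size),
                 rng_seed = as.integer(rng_seed),
                 max_candidates = as.integer(max_candidates)),
            class = "planted_spec")
}

#' Sample a planted-partition hypergraph
#'
#' Every candidate hyperedge of `edge_size` nodes lying within one block is
#' kept with probability `p_in`; every candidate touching at least two
#' blocks is kept with probability `p_out`. With `p_in >> p_out` the blocks
#' are well-separated planted communities.
#'
#' @param spec a [planted_spec()]
#' @return list with `hypergraph` (isolated nodes retained) and `blocks`
#'   (list of ground-truth label vectors)
#' @export
planted_hypergraph <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  n <- sum(spec$block_sizes)
  block <- rep.int(seq_along(spec$block_sizes), spec$block_sizes)
  withr::with_seed(spec$rng_seed, {
    n_cand <- choose(n, spec$edge_size)
    if (n_cand <= spec$max_candidates) {
      cand <- utils::combn(n, spec$edge_size)
      scale <- 1
    } else {
      cand <- replicate(spec$max_candidates,
                        sort(sample.int(n, spec$edge_size)))
      cand <- cand[, !duplicated(t(cand)), drop = FALSE]
      scale <- n_cand / ncol(cand)
    }
    within <- apply(cand, 2L, function(e) length(unique(block[e])) == 1L)
    p <- ifelse(within, pmin(1, spec$p_in * scale), pmin(1, spec$p_out * scale))
    keep <- stats::runif(ncol(cand)) < p
    if (!any(keep)) {
      stop("planted generation produced no hyperedges; increase p_in or block sizes")
    }
    edges <- lapply(which(keep), function(i) cand[, i])
    H <- hypergraph(edges, nodes = seq_len(n))
    list(hypergraph = H,
         blocks = lapply(seq_along(spec$block_sizes),
                         function(b) as.character(which(block == b))))
  })
}

#' Default settings for the mixing-parameter benchmark generator
#'
#' Power-law degrees and community sizes in the spirit of the standard LFR
#' community-detection benchmark, realized as a degree-corrected
#' planted-partition (Chung-Lu style) sampler: each node splits its target
#' degree into a `1 - mu` internal and a `mu` external part, and pairs are
#' wired with probability proportional to the product of the matching
#' degree parts.
#'
#' @param n number of nodes
#' @param avg_degree,max_degree mean and cap of the power-law degree
#'   distribution (exponent `deg_exponent`)
#' @param min_comm,max_comm community-size bounds (power-law exponent
#'   `comm_exponent`)
#' @param deg_exponent,comm_exponent power-law exponents
#' @return a list of generator settings
#' @export
lfr_params <- function(n = 300L, avg_degree = 10, max_degree = 50L,
                       min_comm = 20L, max_comm = 100L,
                       deg_exponent = 2, comm_exponent = 1) {
  list(n = as.integer(n), avg_degree = avg_degree,
       max_degree = as.integer(max_degree), min_comm = as.integer(min_comm),
       max_comm = as.integer(max_comm), deg_exponent = deg_exponent,
       comm_exponent = comm_exponent)
}

# sample k values from a discrete truncated power law p(x) ~ x^(-expo)
sample_power_law <- function(k, lo, hi, expo) {
  support <- lo:hi
  sample(support, k, replace = TRUE, prob = support^(-expo))
}

# choose the smallest lower degree cutoff whose truncated power-law mean is
# closest to the target average degree
power_law_dmin <- function(avg, hi, expo) {
  means <- vapply(1:hi, function(lo) {
    s <- lo:hi
    sum(s * s^(-expo)) / sum(s^(-expo))
  }, numeric(1))
  which.min(abs(means - avg))
}

#' Benchmark graphs across mixing parameters
#'
#' Generates one planted-community benchmark graph per mixing value `mu`
#' (the expected fraction of each node's edges that leave its community)
#' using the degree-corrected planted-partition sampler described in
#' [lfr_params()]. At `mu = 0` communities are (near-)disconnected; as `mu`
#' grows, recovery becomes harder.
#'
#' @param mu_values numeric vector of mixing parameters in `[0, 1)`
#' @param base_params generator settings from [lfr_params()]
#' @param rng_seed integer seed; output is a pure function of the arguments
#' @return list with one element per `mu`: list of `graph` (undirected
#'   [igraph::igraph]), `communities` (list of label vectors) and `mu`
#' @export
lfr_sweep <- function(mu_values, base_params = lfr_params(), rng_seed = 1L) {
  stopifnot(all(mu_values >= 0), all(mu_values < 1))
  bp <- base_params
  withr::with_seed(as.integer(rng_seed), {
    lapply(mu_values, function(mu) lfr_one(mu, bp))
  })
}

lfr_one <- function(mu, bp) {
  n <- bp$n
  # community sizes
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, sample_power_law(1L, bp$min_comm, bp$max_comm,
                                       bp$comm_exponent))
  }
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  if (sizes[length(sizes)] < bp$min_comm && length(sizes) > 1L) {
    sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  comm <- rep.int(seq_along(sizes), sizes)[sample.int(n)]
  # degrees
  dmin <- power_law_dmin(bp$avg_degree, bp$max_degree, bp$deg_exponent)
  deg <- sample_power_law(n, dmin, bp$max_degree, bp$deg_exponent)
  din <- round((1 - mu) * deg)
  dout <- deg - din
  # within-community Chung-Lu wiring
  pairs_u <- integer(0)
  pairs_v <- integer(0)
  for (cid in seq_along(sizes)) {
    mem <- which(comm == cid)
    if (length(mem) < 2L) next
    pr <- utils::combn(mem, 2L)
    s_in <- sum(din[mem])
    if (s_in <= 0) next
    p <- pmin(1, din[pr[1, ]] * din[pr[2, ]] / s_in)
    keep <- stats::runif(ncol(pr)) < p
    pairs_u <- c(pairs_u, pr[1, keep])
    pairs_v <- c(pairs_v, pr[2, keep])
  }
  # cross-community wiring
  pr <- utils::combn(n, 2L)
  cross <- comm[pr[1, ]] != comm[pr[2, ]]
  s_out <- sum(dout)
  if (s_out > 0) {
    p <- pmin(1, dout[pr[1, cross]] * dout[pr[2, cross]] / s_out)
    keep <- stats::runif(sum(cross)) < p
    pairs_u <- c(pairs_u, pr[1, cross][keep])
    pairs_v <- c(pairs_v, pr[2, cross][keep])
  }
  G <- igraph::graph_from_edgelist(cbind(as.character(pairs_u),
                                         as.character(pairs_v)),
                                   directed = FALSE)
  G <- igraph::add_vertices(G, n - igraph::vcount(G),
                            name = as.character(setdiff(seq_len(n),
                                                        c(pairs_u, pairs_v))))
  communities <- lapply(seq_along(sizes),
                        function(cid) as.character(which(comm == cid)))
  list(graph = G, communities = communities, mu = mu)
}
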