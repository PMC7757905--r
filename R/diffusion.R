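# CSR arrays (0-based) for the C++ inner routine, built once per run
hg_csr <- function(H) {
  sizes <- lengths(H$edges)
  list(edge_ptr = as.integer(c(0L, cumsum(sizes))),
       edge_nodes = as.integer(unlist(H$edges, use.names = FALSE) - 1L),
       node_ptr = as.integer(c(0L, cumsum(lengths(H$incidence)))),
       node_edges = as.integer(unlist(H$incidence, use.names = FALSE) - 1L))
}

#' One inner push-relabel run of the hypergraph diffusion
#'
#' Routes the supplied node flows through hyperedges until no node can push:
#' active nodes (excess at least the hyperedge-size threshold) are processed
#' lowest level first, FIFO among equal levels; each scans its incident
#' hyperedges in order and pushes through the first eligible one (see
#' [is_eligible()]), sending `psi` units to every co-member and losing
#' `(|e|-1) * psi` itself, where `psi = min(floor(ex(v)/(|e|-1)), r(e),
#' min_u(2 d_M(u) - m_M(u)))`; otherwise its level rises by one, and at level
#' `h` it retires. Hyperedge flows start at zero (each inner run is a fresh
#' flow problem); total node flow is conserved.
#'
#' @param H a [hypergraph()]
#' @param node_flow numeric vector of non-negative integer flows, named by
#'   node label or in `hg_nodes(H)` order; must satisfy
#'   `node_flow <= 2 * motif_degree(H)`
#' @param params a [crd_params()]; `h` defaults from `phi` and the current
#'   total flow when not set
#' @param trace record every push and relabel event
#' @return list with `level`, `node_flow`, (per-hyperedge) `edge_flow`,
#'   `n_pushes`, `n_relabels`, and when `trace = TRUE` a tibble `trace` of
#'   events
#' @export
hgcrd_inner <- function(H, node_flow, params, trace = FALSE) {
  stopifnot(inherits(H, "hypergraph"), inherits(params, "crd_params"))
  m <- resolve_flow(H, node_flow)
  if (any(m > 2 * H$d)) stop("node_flow must not exceed 2 * motif_degree")
  csr <- hg_csr(H)
  C <- params_C(params)
  h <- params_h(params, sum(m))
  res <- .inner_diffusion_cpp(csr$edge_ptr, csr$edge_nodes, csr$node_ptr,
                              csr$node_edges, as.integer(H$d), as.integer(m),
                              rep(1L, hg_n_edges(H)), C, h, params$alpha,
                              trace)
  tidy_inner(res, H$labels, trace)
}

resolve_flow <- function(H, node_flow) {
  n <- hg_n_nodes(H)
  if (!is.null(names(node_flow))) {
    m <- numeric(n)
    m[hg_index(H, names(node_flow))] <- node_flow
  } else {
    stopifnot(length(node_flow) == n)
    m <- as.numeric(node_flow)
  }
  if (any(m < 0) || any(m != floor(m))) stop("flows must be non-negative integers")
  m
}

tidy_inner <- function(res, labels, trace) {
  out <- list(level = stats::setNames(res$level, labels),
              node_flow = stats::setNames(res$m, labels),
              edge_flow = res$edge_flow,
              n_pushes = res$n_pushes, n_relabels = res$n_relabels)
  if (trace) {
    tr <- res$trace
    out$trace <- tibble::tibble(
      event = c("push", "relabel")[tr$event],
      node = labels[tr$node + 1L],
      edge = ifelse(tr$edge < 0L, NA_integer_, tr$edge + 1L),
      psi = tr$psi, level = tr$level)
  }
  out
}

#' Is a hyperedge eligible for a push from a node?
#'
#' A node `v` may push through hyperedge `e` iff (i) at least `alpha`
#' co-members of `e` sit at a level strictly below `l(v)`, (ii) the residual
#' capacity `min(l(v), C) - m_M(e)` is positive, and (iii) `v`'s excess is at
#' least `|e| - 1` (one unit for every co-member).
#'
#' @param H a [hypergraph()]
#' @param state list with named `node_flow`, `level` vectors and `edge_flow`
#'   (per hyperedge), as returned by [hgcrd_inner()]
#' @param v node label, a member of edge `e`
#' @param e hyperedge index (1-based, in `H`'s edge order)
#' @param params a [crd_params()] (uses `C` and `alpha`)
#' @return logical
#' @export
is_eligible <- function(H, state, v, e, params) {
  stopifnot(inherits(H, "hypergraph"))
  vi <- hg_index(H, v)
  edge <- H$edges[[e]]
  if (!vi %in% edge) stop("node ", v, " is not in hyperedge ", e)
  lev <- state$level[H$labels]
  flow <- state$node_flow[H$labels]
  recv <- setdiff(edge, vi)
  n_below <- sum(lev[recv] < lev[vi])
  resid <- min(lev[vi], params_C(params)) - state$edge_flow[e]
  ex <- max(flow[vi] - H$d[vi], 0)
  (n_below >= params$alpha) && (resid > 0) && (ex >= length(edge) - 1L)
}

# prefix motif conductance along an ordering (internal indices);
# NA where the min-side volume is zero
sweep_prefix_phi <- function(H, ord_int) {
  sizes <- lengths(H$edges)
  total <- sum(H$eta)
  cnt <- integer(length(sizes))
  cut <- 0L
  vol <- 0
  phis <- numeric(length(ord_int))
  for (t in seq_along(ord_int)) {
    v <- ord_int[t]
    for (e in H$incidence[[v]]) {
      if (cnt[e] == 0L) cut <- cut + 1L
      cnt[e] <- cnt[e] + 1L
      if (cnt[e] == sizes[e]) cut <- cut - 1L
    }
    vol <- vol + H$eta[v]
    mv <- min(vol, total - vol)
    phis[t] <- if (mv > 0) cut / mv else NA_real_
  }
  phis
}

#' Sweep cut over diffusion levels
#'
#' Orders the support nodes by level (descending), breaking ties by node
#' flow (descending) then label order (ascending), evaluates the motif
#' conductance of every prefix, and returns the first prefix attaining the
#' minimum. Prefixes whose min-side motif volume is zero are skipped as
#' undefined.
#'
#' @param H a [hypergraph()] on which conductance is evaluated
#' @param levels numeric vector of levels, named by node label or in
#'   `hg_nodes(H)` order
#' @param support node labels to order (typically the nodes the diffusion
#'   touched); defaults to all nodes
#' @param node_flow optional flows for tie-breaking, same conventions as
#'   `levels`
#' @return an object of class `sweep_result`: list with `order` (labels),
#'   `profile` (tibble: node, level, prefix motif conductance), `best_set`,
#'   `best_phi`
#' @export
sweep_cut <- function(H, levels, support = NULL, node_flow = NULL) {
  stopifnot(inherits(H, "hypergraph"))
  lev <- resolve_vec(H, levels)
  flow <- if (is.null(node_flow)) numeric(hg_n_nodes(H)) else resolve_vec(H, node_flow)
  sup <- if (is.null(support)) seq_len(hg_n_nodes(H)) else sort(unique(hg_index(H, support)))
  if (length(sup) == 0L) stop("support must be nonempty")
  ord <- sup[order(-lev[sup], -flow[sup], sup)]
  phis <- sweep_prefix_phi(H, ord)
  if (all(is.na(phis))) {
    stop("sweep failed: every prefix has undefined motif conductance")
  }
  best <- which.min(phis) # which.min ignores NA; first minimizer on ties
  structure(list(
    order = H$labels[ord],
    profile = tibble::tibble(node = H$labels[ord], level = lev[ord],
                             node_flow = flow[ord], phi = phis),
    best_set = H$labels[ord[seq_len(best)]],
    best_phi = phis[best]), class = "sweep_result")
}

resolve_vec <- function(H, x) {
  if (!is.null(names(x))) {
    out <- numeric(hg_n_nodes(H))
    out[hg_index(H, names(x))] <- x
    out
  } else {
    stopifnot(length(x) == hg_n_nodes(H))
    as.numeric(x)
  }
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep cut: best prefix of %d node(s), motif conductance %.4g\n",
              length(x$best_set), x$best_phi))
  invisible(x)
}

#' Nodes retaining excess flow after a diffusion run
#'
#' The set `{v : m_M(v) >= d_M(v)}` of nodes whose flow meets or exceeds
#' their motif degree at the end of an inner run — the theoretically
#' characterized bottlenecked cluster. Nodes carrying no flow and belonging
#' to no hyperedge are excluded.
#'
#' @param H a [hypergraph()]
#' @param node_flow flows after an inner run, named by label or in
#'   `hg_nodes(H)` order
#' @return character vector of node labels
#' @export
excess_cluster <- function(H, node_flow) {
  m <- resolve_vec(H, node_flow)
  keep <- m >= H$d & !(H$d == 0 & m == 0)
  H$labels[keep]
}

# shared outer loop: flow runs on `Hflow` with node capacities `d` and
# per-hyperedge capacity multipliers `ew`; sweeps are evaluated by motif
# conductance on `Heval` (same node indexing)
crd_engine <- function(Hflow, Heval, d, ew, seed_int, params, trace,
                       algorithm) {
  csr <- hg_csr(Hflow)
  n <- hg_n_nodes(Hflow)
  C <- params_C(params)
  if (d[seed_int] <= 0) {
    stop("seed node '", Hflow$labels[seed_int],
         "' belongs to no motif instance")
  }
  m <- numeric(n)
  m[seed_int] <- d[seed_int]
  best_set_int <- NULL
  best_phi <- Inf
  best_sweep <- NULL
  hist <- vector("list", params$t + 1L)
  traces <- if (trace) vector("list", params$t + 1L)
  terminated_by <- "iteration-cap"
  iterations <- 0L
  excess_set <- integer(0)
  for (j in 0:params$t) {
    m <- 2 * m
    h <- params_h(params, sum(m))
    res <- .inner_diffusion_cpp(csr$edge_ptr, csr$edge_nodes, csr$node_ptr,
                                csr$node_edges, as.integer(d), as.integer(m),
                                as.integer(ew), C, h, params$alpha, trace)
    m <- res$m
    iterations <- j + 1L
    if (trace) traces[[j + 1L]] <- tidy_inner(res, Hflow$labels, TRUE)$trace
    support <- union(which(res$level > 0L | m > 0), seed_int)
    sw <- tryCatch(
      sweep_cut(Heval, res$level, Heval$labels[support], m),
      error = function(e) NULL)
    if (!is.null(sw) && sw$best_phi < best_phi) {
      best_phi <- sw$best_phi
      best_set_int <- hg_index(Heval, sw$best_set)
      best_sweep <- sw
    }
    excess_set <- which(m >= d & !(d == 0 & m == 0))
    total_before <- sum(m)
    m <- pmin(m, d)
    retained <- sum(m)
    target <- 2 * d[seed_int] * 2^j
    hist[[j + 1L]] <- tibble::tibble(
      iteration = j, h = h, n_pushes = res$n_pushes,
      n_relabels = res$n_relabels, flow_total = total_before,
      flow_retained = retained, stop_threshold = target / params$tau,
      sweep_phi = if (is.null(sw)) NA_real_ else sw$best_phi,
      sweep_size = if (is.null(sw)) NA_integer_ else length(sw$best_set))
    if (retained <= target / params$tau) {
      terminated_by <- "bottleneck"
      break
    }
  }
  if (is.null(best_set_int)) {
    stop("diffusion produced no sweep prefix with defined motif conductance")
  }
  cluster <- Heval$labels[sort(best_set_int)]
  structure(list(
    cluster = cluster,
    phi = best_phi,
    cut = motif_cut(Heval, cluster),
    volume = motif_volume(Heval, cluster),
    excess_cluster = Hflow$labels[sort(excess_set)],
    iterations_run = iterations,
    terminated_by = terminated_by,
    history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
    sweep = best_sweep,
    seed = Hflow$labels[seed_int],
    algorithm = algorithm,
    params = params,
    trace = if (trace) traces[seq_len(iterations)]),
    class = "crd_cluster")
}

#' HG-CRD: local hypergraph clustering by capacity-releasing diffusion
#'
#' Finds a low motif-conductance cluster around a seed node by repeatedly
#' (i) doubling all node flows, (ii) routing them with the push-relabel
#' inner run ([hgcrd_inner()]), (iii) sweep-cutting the resulting levels and
#' keeping the best prefix seen so far, and (iv) truncating each node's flow
#' to its motif degree. The loop stops early when truncation removed so much
#' excess that the retained flow is at most `1/tau` of what doubling alone
#' would give — the capacity-releasing signature of a bottleneck at the
#' cluster boundary.
#'
#' @param H a [hypergraph()] (e.g. a motif hypergraph from
#'   [enumerate_motifs()], or any hypergraph of interactions)
#' @param seed label of the starting node; must belong to >= 1 hyperedge
#' @param params a [crd_params()]
#' @param trace keep per-iteration push/relabel event logs
#' @return an object of class `crd_cluster`: list with `cluster` (node
#'   labels), `phi` (its motif conductance), `cut`, `volume`,
#'   `excess_cluster` (nodes still holding flow >= degree at termination),
#'   `iterations_run`, `terminated_by` (`"bottleneck"` or
#'   `"iteration-cap"`), `history` (per-iteration tibble), `sweep` (the best
#'   [sweep_cut()] result), `seed`, `params`
#' @examples
#' H <- metabolic_fixture()
#' res <- hgcrd(H, seed = 7, crd_params(C = 2, h = 2, tau = 2, t = 5))
#' res$cluster
#' round(res$phi, 2)
#' @export
hgcrd <- function(H, seed, params = crd_params(phi = 0.1), trace = FALSE) {
  stopifnot(inherits(H, "hypergraph"), inherits(params, "crd_params"))
  seed_int <- hg_index(H, seed)
  if (H$eta[seed_int] == 0L) {
    stop("seed node '", as.character(seed), "' belongs to no hyperedge")
  }
  crd_engine(H, H, H$d, rep(1L, hg_n_edges(H)), seed_int, params, trace,
             algorithm = "hgcrd")
}

#' CRD: edge-based capacity-releasing diffusion
#'
#' The original edge diffusion, realized exactly as [hgcrd()] on the
#' 2-uniform hypergraph whose hyperedges are the graph's edges: motif
#' degrees reduce to ordinary degrees and hyperedge eligibility reduces to
#' `l(v) > l(u)`. `alpha` must be 1 for 2-node hyperedges.
#'
#' @param G an undirected [igraph::igraph] graph
#' @inheritParams hgcrd
#' @return a `crd_cluster`, see [hgcrd()]
#' @export
crd <- function(G, seed, params = crd_params(phi = 0.1), trace = FALSE) {
  stopifnot(igraph::is_igraph(G))
  if (params$alpha != 1L) stop("alpha must be 1 for the edge diffusion (k = 2)")
  H <- as_edge_hypergraph(G)
  res <- hgcrd(H, seed, params, trace)
  res$algorithm <- "crd"
  res
}

#' CRD-M: edge diffusion weighted by the motif adjacency matrix
#'
#' Enumerates the motif instances of `G`, builds the motif adjacency matrix
#' W_M ([motif_adjacency()]), and runs the edge diffusion on the graph of
#' nonzero pairs with every quantity scaled by the weights: edge `(u, v)`
#' carries `W_M(u, v)` times the usual capacity, and node capacities use the
#' weighted degree `sum_j W_M(v, j)` (which equals the motif degree for
#' 3-node motifs). Sweep prefixes are scored by motif conductance on the
#' motif hypergraph, so results are directly comparable with [hgcrd()].
#'
#' @param G an [igraph::igraph] graph matching the motif's directedness
#' @param motif a [motif_spec()] or its name
#' @inheritParams hgcrd
#' @return a `crd_cluster`, see [hgcrd()]
#' @export
crd_m <- function(G, motif = motif_spec("triangle"), seed,
                  params = crd_params(phi = 0.1), trace = FALSE) {
  if (is.character(motif)) motif <- motif_spec(motif)
  if (params$alpha != 1L) stop("alpha must be 1 for the edge diffusion (k = 2)")
  HM <- enumerate_motifs(G, motif)
  W <- motif_adjacency_matrix(HM)
  TW <- Matrix::triu(W, k = 1)
  nz <- Matrix::which(TW > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("no motif instances in G")
  edges <- lapply(seq_len(nrow(nz)), function(i) HM$labels[nz[i, ]])
  Hflow <- hypergraph(edges, nodes = HM$labels)
  # node indexing of Hflow matches HM: same label set, same ordering rule
  stopifnot(identical(Hflow$labels, HM$labels))
  ew <- TW[nz]
  wdeg <- as.numeric(Matrix::rowSums(W))
  seed_int <- hg_index(HM, seed)
  if (wdeg[seed_int] <= 0) {
    stop("seed node '", as.character(seed), "' belongs to no motif instance")
  }
  # hyperedge order in Hflow may differ from nz order after construction:
  # reorder weights to Hflow's edge order
  key_nz <- paste(pmin(nz[, 1], nz[, 2]), pmax(nz[, 1], nz[, 2]))
  key_fl <- vapply(Hflow$edges, function(e) paste(e[1], e[2]), character(1))
  ew <- ew[match(key_fl, key_nz)]
  res <- crd_engine(Hflow, HM, wdeg, ew, seed_int, params, trace,
                    algorithm = "crd_m")
  res$motif <- motif$name
  res
}

#' @exportS3Method base::print
print.crd_cluster <- function(x, ...) {
  cat(sprintf("%s cluster from seed '%s': %d node(s), motif conductance %.4g\n",
              x$algorithm, x$seed, length(x$cluster), x$phi))
  cat(sprintf("  cut %d hyperedge(s), motif volume %d; %d iteration(s), stopped by %s\n",
              x$cut, x$volume, x$iterations_run, x$terminated_by))
  cat("  nodes:", paste(x$cluster, collapse = " "), "\n")
  invisible(x)
}
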