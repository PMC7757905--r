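# replay a recorded event log, re-checking every bound the inner run promises
replay_trace <- function(H, m0, trace, C, h) {
  m <- m0
  ef <- numeric(hg_n_edges(H))
  lev <- stats::setNames(numeric(hg_n_nodes(H)), hg_nodes(H))
  edges <- hg_edges(H)
  for (i in seq_len(nrow(trace))) {
    ev <- trace[i, ]
    if (ev$event == "push") {
      e <- edges[[ev$edge]]
      expect_true(ev$psi >= 1 && ev$psi == floor(ev$psi))
      recv <- setdiff(e, ev$node)
      ef[ev$edge] <- ef[ev$edge] + ev$psi
      expect_lte(ef[ev$edge], C)
      m[ev$node] <- m[ev$node] - length(recv) * ev$psi
      expect_gte(m[ev$node], 0)
      for (u in recv) {
        m[u] <- m[u] + ev$psi
        expect_lte(m[u], 2 * unname(motif_degree(H, u)))
      }
    } else {
      expect_equal(ev$level, lev[ev$node] + 1, ignore_attr = TRUE)
      lev[ev$node] <- ev$level
      expect_lte(ev$level, h)
    }
  }
  list(m = m, edge_flow = ef, level = lev)
}

test_that("a single-hyperedge inner run follows the hand trace", {
  H <- hypergraph(list(c("a", "b", "c")))
  p <- crd_params(C = 2, h = 3, tau = 2, t = 1, alpha = 1)
  res <- hgcrd_inner(H, c(a = 4, b = 0, c = 0), p, trace = TRUE)
  # a relabels once, then pushes psi = min(floor(2/2), min(1,2) - 0, 4) = 1
  expect_equal(unname(res$level), c(1, 0, 0))
  expect_equal(unname(res$node_flow), c(2, 1, 1))
  expect_equal(res$edge_flow, 1)
  expect_equal(res$n_pushes, 1)
  expect_equal(res$n_relabels, 1)
  expect_equal(res$trace$event, c("relabel", "push"))
})

test_that("an inner run with no active node leaves levels and flows untouched", {
  H <- hypergraph(list(c(1, 2, 3), c(2, 3, 4)))
  m0 <- motif_degree(H) + 1 # below the d + (k-1) activation threshold
  res <- hgcrd_inner(H, m0, crd_params(C = 2, h = 3, tau = 2, t = 1))
  expect_true(all(res$level == 0))
  expect_equal(res$node_flow, stats::setNames(as.numeric(m0), names(m0)))
  expect_true(all(res$edge_flow == 0))
})

test_that("eligibility needs lower levels, residual capacity and enough excess", {
  H <- hypergraph(list(c("a", "b", "c")))
  p <- crd_params(C = 2, h = 3, tau = 2, t = 1, alpha = 1)
  st <- list(node_flow = c(a = 4, b = 0, c = 0), level = c(a = 1, b = 0, c = 0),
             edge_flow = 0)
  expect_true(is_eligible(H, st, "a", 1, p))
  st$edge_flow <- 2 # capacity exhausted
  expect_false(is_eligible(H, st, "a", 1, p))
  st$edge_flow <- 0
  st$level <- c(a = 0, b = 0, c = 0) # no receiver below
  expect_false(is_eligible(H, st, "a", 1, p))
  st$level <- c(a = 1, b = 0, c = 1) # one below but alpha = 2
  p2 <- crd_params(C = 2, h = 3, tau = 2, t = 1, alpha = 2)
  expect_false(is_eligible(H, st, "a", 1, p2))
  expect_true(is_eligible(H, st, "a", 1, p))
  st$node_flow <- c(a = 3, b = 0, c = 0) # excess 1 < k - 1
  expect_false(is_eligible(H, st, "a", 1, p))
})

test_that("inner runs conserve flow and respect every capacity bound", {
  set.seed(61)
  for (rep in 1:15) {
    H <- rand_hypergraph(sample(5:14, 1), sample(3:20, 1))
    d <- unname(motif_degree(H))
    m0 <- vapply(d, function(x) sample(0:(2 * x), 1), numeric(1))
    C <- sample(2:4, 1)
    h <- sample(2:5, 1)
    p <- crd_params(C = C, h = h, tau = 2, t = 1, alpha = 1)
    res <- hgcrd_inner(H, m0, p, trace = TRUE)
    expect_equal(sum(res$node_flow), sum(m0)) # conservation
    expect_true(all(res$edge_flow >= 0 & res$edge_flow <= C))
    expect_true(all(res$node_flow >= 0 & res$node_flow <= 2 * d))
    expect_true(all(res$level >= 0 & res$level <= h))
    expect_true(all(res$node_flow == floor(res$node_flow)))
    m0named <- stats::setNames(m0, hg_nodes(H))
    fin <- replay_trace(H, m0named, res$trace, C, h) # per-event bounds
    expect_equal(fin$m[hg_nodes(H)], res$node_flow[hg_nodes(H)])
    expect_equal(fin$edge_flow, res$edge_flow)
    expect_equal(unname(fin$level[hg_nodes(H)]), unname(res$level))
  }
})

test_that("sweep cut minimizes prefix motif conductance (oracle recheck)", {
  set.seed(71)
  for (rep in 1:20) {
    H <- rand_hypergraph(sample(5:12, 1), sample(3:12, 1))
    lev <- sample(0:4, hg_n_nodes(H), replace = TRUE)
    flow <- sample(0:6, hg_n_nodes(H), replace = TRUE)
    sup <- sample(hg_nodes(H), sample(2:hg_n_nodes(H), 1))
    sw <- tryCatch(sweep_cut(H, lev, sup, flow), error = function(e) NULL)
    oracle <- vapply(seq_along(if (is.null(sw)) character(0) else sw$order),
                     function(k) {
                       pre <- sw$order[seq_len(k)]
                       tryCatch(motif_conductance(H, pre),
                                error = function(e) NA_real_)
                     }, numeric(1))
    if (is.null(sw)) next
    expect_equal(sw$profile$phi, oracle)
    expect_equal(sw$best_phi, min(oracle, na.rm = TRUE))
    expect_equal(sw$best_set, sw$order[seq_len(which.min(oracle))])
  }
})

test_that("sweep errors when every prefix is undefined", {
  H <- hypergraph(list(c("c", "d")), nodes = c("a", "b"))
  expect_error(sweep_cut(H, rep(1, 4), support = c("a", "b")), "undefined")
})

test_that("the diffusion stays inside a disconnected component", {
  H <- hypergraph(list(c(0, 1, 2), c(3, 4, 5)))
  res <- hgcrd(H, 0, crd_params(C = 2, h = 3, tau = 2, t = 4))
  expect_setequal(res$cluster, c("0", "1", "2"))
  expect_equal(res$phi, 0)
  expect_equal(res$cut, 0)
})

test_that("t = 0 with huge tau runs exactly one inner iteration", {
  H <- metabolic_fixture()
  res <- hgcrd(H, 7, crd_params(C = 2, h = 2, tau = 1e9, t = 0))
  expect_equal(res$iterations_run, 1L)
  expect_equal(res$terminated_by, "iteration-cap") # tau too large to trigger
  expect_gt(length(res$cluster), 0)
})

test_that("seeds without any hyperedge are rejected", {
  H <- hypergraph(list(c(1, 2, 3)), nodes = 4)
  expect_error(hgcrd(H, 4, fig1_params()), "no hyperedge")
  expect_error(hgcrd(H, 99, fig1_params()), "unknown node")
})

test_that("the excess cluster is the flow >= degree set, minus untouched isolates", {
  H <- hypergraph(list(c(0, 1, 3), c(0, 1, 2), c(0, 2, 3), c(1, 4, 6)),
                  nodes = 5)
  d <- motif_degree(H)
  m <- stats::setNames(numeric(hg_n_nodes(H)), hg_nodes(H))
  m["0"] <- d["0"] # seed-only flow
  expect_equal(excess_cluster(H, m), "0")
  m[c("1", "2", "3")] <- d[c("1", "2", "3")] + 1
  expect_setequal(excess_cluster(H, m), c("0", "1", "2", "3"))
  # isolated node 5 has d = 0 and m = 0: excluded by support filtering
  expect_false("5" %in% excess_cluster(H, m))
})

test_that("hgcrd reports per-iteration history consistent with its result", {
  H <- metabolic_fixture()
  res <- hgcrd(H, 7, fig1_params())
  expect_equal(res$phi, motif_conductance(H, res$cluster))
  expect_lte(res$iterations_run, fig1_params()$t + 1)
  expect_equal(nrow(res$history), res$iterations_run)
  expect_true(all(diff(res$history$iteration) == 1))
  g <- glance(res)
  expect_equal(g$phi, res$phi)
  td <- tidy(res)
  expect_true(all(res$cluster %in% td$node[td$in_cluster]))
})

test_that("edge diffusion equals the 2-uniform hypergraph diffusion push-for-push", {
  set.seed(81)
  n_done <- 0
  for (rep in 1:20) {
    if (n_done >= 10) break
    G <- rand_gnp(sample(6:12, 1), 0.4)
    if (igraph::ecount(G) < 3) next
    seed <- igraph::V(G)$name[which.max(igraph::degree(G))]
    p <- crd_params(C = 2, h = 3, tau = 2, t = 4, alpha = 1)
    a <- tryCatch(crd(G, seed, p, trace = TRUE), error = function(e) NULL)
    b <- tryCatch(hgcrd(as_edge_hypergraph(G), seed, p, trace = TRUE),
                  error = function(e) NULL)
    if (is.null(a) && is.null(b)) next
    expect_false(is.null(a) || is.null(b))
    expect_equal(a$cluster, b$cluster)
    expect_equal(a$phi, b$phi)
    expect_equal(length(a$trace), length(b$trace))
    for (i in seq_along(a$trace)) expect_equal(a$trace[[i]], b$trace[[i]])
    n_done <- n_done + 1
  }
  expect_gte(n_done, 10)
})

test_that("motif-weighted edge diffusion scales capacities and degrees by W_M", {
  # single triangle: weights all 1, crd_m behaves exactly like crd
  K3 <- rand_gnp(3, 1)
  p <- crd_params(C = 2, h = 2, tau = 2, t = 2, alpha = 1)
  a <- crd_m(K3, "triangle", "1", p)
  b <- crd(K3, "1", p)
  expect_equal(a$cluster, b$cluster)

  # two triangles sharing an edge: the shared pair carries weight 2
  G <- igraph::graph_from_edgelist(
    cbind(c("1", "2", "3", "2", "4"), c("2", "3", "1", "4", "3")),
    directed = FALSE)
  H <- enumerate_motifs(G, "triangle")
  W <- motif_adjacency(H)
  id <- igraph::get_edge_ids(W, c("2", "3"))
  expect_equal(igraph::E(W)$weight[id], 2)
  wdeg <- igraph::strength(W, weights = igraph::E(W)$weight)
  expect_equal(unname(wdeg[hg_nodes(H)]), unname(motif_degree(H)))
  res <- crd_m(G, "triangle", "2", p)
  expect_true(all(res$cluster %in% hg_nodes(H)))
  expect_equal(res$phi, motif_conductance(H, res$cluster))
})
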