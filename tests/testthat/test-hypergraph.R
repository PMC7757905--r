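test_that("construction builds a consistent incidence index", {
  H <- hypergraph(list(c(1, 2, 5), c(2, 3, 5), c(2, 3, 5)), nodes = 9)
  expect_equal(hg_n_nodes(H), 5) # 1,2,3,5 plus isolated 9
  expect_equal(hg_n_edges(H), 3) # duplicates kept as distinct entries
  expect_equal(H$k_uniform, 3L)
  # edge i appears in incidence[v] iff v is in edges[i]
  for (v in seq_len(hg_n_nodes(H))) {
    for (i in seq_len(hg_n_edges(H))) {
      expect_equal(i %in% H$incidence[[v]], v %in% H$edges[[i]])
    }
  }
  expect_equal(unname(hyperedge_count(H, 9)), 0L) # isolated node allowed
  expect_error(hypergraph(list(c(3, 3, 4))), "repeated")
  expect_error(hypergraph(list(5)), "fewer than 2")
})

test_that("motif degree counts hyperedge end points", {
  H <- metabolic_fixture()
  expect_equal(unname(motif_degree(H, 7)), 6L) # in {1,6,7},{1,7,8},{5,6,7}
  expect_equal(unname(motif_degree(hypergraph(list(c("a", "b", "c"))), "a")), 2L)
  Hiso <- hypergraph(list(c(1, 2)), nodes = 3)
  expect_equal(unname(motif_degree(Hiso, 3)), 0L)
  # non-uniform: per-edge-additive extension sums |e| - 1
  Hnu <- hypergraph(list(c(1, 2, 3, 4), c(1, 2)))
  expect_equal(unname(motif_degree(Hnu, 1)), 4L)
  expect_equal(unname(motif_degree(Hnu, 3)), 3L)
  expect_error(motif_degree(H, 99), "unknown node")
})

test_that("motif volume counts end point incidences, scaled variant uses degrees", {
  H <- metabolic_fixture()
  expect_equal(motif_volume(H, c(1, 6, 7, 8)), 11L)
  expect_equal(motif_volume(H, character(0)), 0L)
  expect_equal(motif_volume(H, hg_nodes(H)), 27L) # 9 edges x 3 end points
  expect_equal(motif_volume(H, c(1, 6, 7, 8), scaled = TRUE),
               2L * motif_volume(H, c(1, 6, 7, 8)))
})

test_that("handshake and volume-complement identities hold on random hypergraphs", {
  set.seed(11)
  for (rep in 1:30) {
    H <- rand_hypergraph(sample(4:15, 1), sample(1:20, 1))
    total <- sum(lengths(H$edges))
    expect_equal(sum(hyperedge_count(H)), total)
    S <- sample(hg_nodes(H), sample.int(hg_n_nodes(H), 1))
    expect_equal(motif_volume(H, S) + motif_volume(H, setdiff(hg_nodes(H), S)),
                 total)
    expect_equal(motif_volume(H, S), naive_motif_vol(H, S))
  }
})

test_that("write followed by read restores the hypergraph", {
  set.seed(21)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  for (rep in 1:20) {
    H <- rand_hypergraph(sample(3:12, 1), sample(1:15, 1))
    write_hypergraph(H, tmp)
    H2 <- read_hypergraph(tmp)
    expect_equal(hg_n_edges(H2), hg_n_edges(H))
    expect_equal(edge_multiset(H2), edge_multiset(H))
    # non-isolated node sets agree (isolated nodes are not representable)
    expect_true(all(hg_nodes(H2) %in% hg_nodes(H)))
  }
  write_hypergraph(hypergraph(list()), tmp)
  expect_equal(hg_n_edges(read_hypergraph(tmp)), 0)
})

test_that("reader accepts comments and a count header, rejects malformed lines", {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c("# comment", "% also a comment", "4 3", "1 2 5", "2 3 5",
               "1 3 5"), tmp)
  H <- read_hypergraph(tmp) # "4 3" matches counts -> header, ignored
  expect_equal(hg_n_edges(H), 3)
  expect_equal(hg_n_nodes(H), 4)

  writeLines(c("1 2", "3 4"), tmp) # 2-token line that is NOT a header
  expect_equal(hg_n_edges(read_hypergraph(tmp)), 2)

  writeLines(c("1 2 3", "3 3 4"), tmp)
  expect_error(read_hypergraph(tmp), "line 2")
  writeLines(c("1 2 3", "7"), tmp)
  expect_error(read_hypergraph(tmp), "line 2")
  expect_error(read_hypergraph(tempfile()), "no such file")
})

test_that("edge list and community readers parse the standard dialects", {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c("# src dst", "1 2", "2 3 1.5"), tmp)
  G <- read_edgelist(tmp)
  expect_equal(igraph::ecount(G), 2)
  expect_false(igraph::is_directed(G))
  expect_equal(igraph::E(G)$weight, c(1, 1.5))
  Gd <- read_edgelist(tmp, directed = TRUE)
  expect_true(igraph::is_directed(Gd))

  writeLines(c("1 2 3", "4 5"), tmp)
  comms <- read_communities(tmp)
  expect_equal(comms, list(c("1", "2", "3"), c("4", "5")))
  write_communities(comms, tmp)
  expect_equal(read_communities(tmp), comms)
})

test_that("an undirected graph converts to its 2-uniform edge hypergraph", {
  G <- rand_gnp(8, 0.4)
  H <- as_edge_hypergraph(G)
  expect_equal(hg_n_edges(H), igraph::ecount(G))
  expect_equal(H$k_uniform, 2L)
  deg <- igraph::degree(G)
  expect_equal(unname(motif_degree(H, igraph::V(G)$name)), unname(deg))
})
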