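mk_records <- function(...) {
  path <- write_tsv_lines(c(...))
  read_interactions(path)
}

test_that("interaction records parse with kind invariants enforced", {
  rec <- mk_records("r1\tp1;p2\tbinary\ttwo hybrid\tdbX",
                    "r2\tp1;p2;p3\tcomplex\taffinity chromatography\tdbX")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$kind, c("binary", "complex"))
  expect_equal(rec$members[[1]], c("p1", "p2"))

  expect_warning(rec2 <- mk_records("r1\tp1;p2\tcomplex\tx\tdbX"),
                 "reclassified as binary")
  expect_equal(rec2$kind, "binary")
  expect_warning(rec3 <- mk_records("r1\tp1\tbinary\tx\tdbX",
                                    "r2\ta;b\tbinary\tx\tdbX"),
                 "skipped")
  expect_equal(nrow(rec3), 1L)
  expect_error(read_interactions(write_tsv_lines("r1\tonly3\tcols")),
               "malformed line 1")
})

test_that("predicted-interaction filter is a case-insensitive substring match", {
  rec <- mk_records("r1\ta;b\tbinary\tpredicted by homology\tdb",
                    "r2\ta;c\tbinary\ttwo hybrid\tdb",
                    "r3\ta;d\tbinary\tInterologs Mapping\tdb",
                    "r4\ta;e\tbinary\tour confirmational text mining run\tdb",
                    "r5\ta;f\tbinary\tanti tag coimmunoprecipitation\tdb")
  kept <- filter_predicted(rec)
  expect_equal(kept$record_id, c("r2", "r5"))
})

test_that("matrix expansion yields k(k-1)/2 pairs with merged provenance", {
  rec <- mk_records("r1\tx;y;z\tcomplex\tm\tdb")
  pairs <- expand_complexes(rec)
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$has_complex) && !any(pairs$has_binary))

  # binary + complex over the same pair -> both provenance flags
  rec2 <- mk_records("r1\ta;b\tbinary\tm\tdb", "r2\ta;b;c\tcomplex\tm\tdb")
  p2 <- expand_complexes(rec2)
  ab <- p2[p2$a == "a" & p2$b == "b", ]
  expect_true(ab$has_binary && ab$has_complex)

  # duplicate member ids never produce self-pairs
  rec3 <- mk_records("r1\ta;a;b\tcomplex\tm\tdb")
  p3 <- expand_complexes(rec3)
  expect_equal(nrow(p3), 1L)
  expect_true(all(p3$a != p3$b))
})

test_that("expansion size is exactly k(k-1)/2 for k up to 12", {
  for (k in 3:12) {
    rec <- mk_records(sprintf("r1\t%s\tcomplex\tm\tdb",
                              paste(sprintf("m%02d", 1:k), collapse = ";")))
    expect_equal(nrow(expand_complexes(rec)), k * (k - 1) / 2)
  }
})

test_that("network construction deduplicates and keeps isolated extras", {
  pairs <- data.frame(a = c("a", "b", "a", "a"), b = c("b", "c", "c", "b"),
                      has_binary = c(TRUE, TRUE, TRUE, FALSE),
                      has_complex = c(FALSE, FALSE, FALSE, TRUE))
  net <- build_network(pairs, extra_nodes = "lonely")
  expect_setequal(network_nodes(net), c("a", "b", "c", "lonely"))
  e <- network_edges(net)
  expect_equal(nrow(e), 3L)
  ab <- e[(e$a == "a" & e$b == "b") | (e$a == "b" & e$b == "a"), ]
  expect_true(ab$has_binary && ab$has_complex)

  empty <- build_network(data.frame(a = character(0), b = character(0)))
  expect_length(network_nodes(empty), 0L)
})

test_that("density and components match the undirected definitions", {
  k4 <- build_network(data.frame(a = c("a","a","a","b","b","c"),
                                 b = c("b","c","d","c","d","d")))
  expect_equal(network_stats(k4)$density, 1.0)

  path_net <- build_network(data.frame(a = c("a", "b"), b = c("b", "c")),
                            extra_nodes = "d")
  st <- network_stats(path_net)
  expect_equal(sort(lengths(st$components)), c(1L, 3L))
  expect_equal(unname(st$degrees[c("a", "b", "d")]), c(1, 2, 0))

  lonely <- build_network(data.frame(a = character(0), b = character(0)),
                          extra_nodes = "x")
  expect_warning(st1 <- network_stats(lonely), "density undefined")
  expect_equal(st1$density, 0)
})

test_that("published subnetwork sizes give the published density", {
  expect_equal(round(100 * graph_density(4009, 290496), 1), 3.6)
})

test_that("BFS distances report minima, attaining counts and direct sources", {
  net <- build_network(data.frame(a = c("a", "b"), b = c("b", "c")))
  d <- shortest_distances(net, "a")
  expect_equal(d$dist[d$id == "c"], 2)
  expect_equal(d$dist[d$id == "a"], 0)

  # node adjacent to two sources
  tri <- build_network(data.frame(a = c("s1", "s2"), b = c("x", "x")))
  dx <- shortest_distances(tri, c("s1", "s2"))
  expect_equal(dx$dist[dx$id == "x"], 1)
  expect_equal(dx$n_at_min[dx$id == "x"], 2L)
  expect_setequal(dx$sources_at_1[[which(dx$id == "x")]], c("s1", "s2"))

  # star: sources on two leaves, query the third leaf (frozen from the
  # brute-force all-pairs table of the 4-node star)
  star <- build_network(data.frame(a = rep("hub", 3), b = c("l1", "l2", "l3")))
  ds <- shortest_distances(star, c("l1", "l2"))
  expect_equal(ds$dist[ds$id == "l3"], 2)
  expect_equal(ds$n_at_min[ds$id == "l3"], 2L)

  expect_warning(dn <- shortest_distances(net, "ghost"), "no source")
  expect_true(all(is.na(dn$dist)))
})

test_that("BFS agrees with Floyd-Warshall on random graphs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    pairs <- random_pairs(n)
    if (nrow(pairs) == 0L) next
    net <- build_network(pairs, extra_nodes = sprintf("n%02d", 1:n))
    nodes <- network_nodes(net)
    fw <- fw_distances(nodes, pairs$a, pairs$b)
    src <- sample(nodes, sample(1:3, 1))
    d <- shortest_distances(net, src)
    want <- apply(fw[src, , drop = FALSE], 2L, min)
    got <- ifelse(is.na(d$dist), Inf, d$dist)
    expect_equal(unname(got[match(names(want), d$id)]), unname(want))
  }
})

test_that("distances are symmetric, metric, and monotone under edge addition", {
  set.seed(7)
  for (rep in 1:20) {
    pairs <- random_pairs(10, p_edge = 0.3)
    if (nrow(pairs) < 2L) next
    nodes <- sprintf("n%02d", 1:10)
    net <- build_network(pairs, extra_nodes = nodes)
    d <- igraph::distances(net$graph, algorithm = "unweighted")
    expect_equal(d, t(d))
    finite <- d; finite[!is.finite(finite)] <- 1e6
    for (i in 1:10) expect_true(all(finite <= outer(finite[, i], finite[i, ], `+`) + 1e-9))
    # add one edge: no distance may increase
    non_edges <- which(d > 1 & upper.tri(d), arr.ind = TRUE)
    if (nrow(non_edges) == 0L) next
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    aug <- rbind(pairs[, c("a", "b")],
                 data.frame(a = rownames(d)[pick[1]], b = colnames(d)[pick[2]]))
    net2 <- build_network(aug, extra_nodes = nodes)
    d2 <- igraph::distances(net2$graph, algorithm = "unweighted")[rownames(d), colnames(d)]
    expect_true(all(d2 <= d + 1e-9))
  }
})

test_that("shortest-path subnetwork keeps exactly the geodesic nodes", {
  # single geodesic a-x-b
  net <- build_network(data.frame(a = c("a", "x"), b = c("x", "b")))
  sub <- extract_subnetwork(net, "a", "b")
  expect_setequal(network_nodes(sub), c("a", "x", "b"))
  expect_equal(nrow(network_edges(sub)), 2L)

  # two parallel geodesics: both intermediates kept
  net2 <- build_network(data.frame(a = c("a", "x", "a", "y"),
                                   b = c("x", "b", "y", "b")))
  expect_setequal(network_nodes(extract_subnetwork(net2, "a", "b")),
                  c("a", "x", "y", "b"))

  # longer alternative path loses to the shorter geodesic
  net3 <- build_network(data.frame(a = c("a", "x", "y", "a", "z"),
                                   b = c("x", "y", "b", "z", "b")))
  expect_setequal(network_nodes(extract_subnetwork(net3, "a", "b")),
                  c("a", "z", "b"))
})

test_that("subnetwork node sets are minimal on random instances", {
  set.seed(5)
  for (rep in 1:20) {
    pairs <- random_pairs(10, p_edge = 0.3)
    if (nrow(pairs) == 0L) next
    nodes <- sprintf("n%02d", 1:10)
    net <- build_network(pairs, extra_nodes = nodes)
    A <- sample(nodes, 2); B <- sample(setdiff(nodes, A), 2)
    sub <- extract_subnetwork(net, A, B)
    d <- igraph::distances(net$graph, algorithm = "unweighted")
    for (v in setdiff(network_nodes(sub), c(A, B))) {
      on_some <- any(vapply(A, function(a) any(vapply(B, function(b) {
        is.finite(d[a, b]) && d[a, v] + d[v, b] == d[a, b]
      }, logical(1))), logical(1)))
      expect_true(on_some)
    }
  }
})

test_that("candidate network features mirror the low-degree exemplar", {
  # hub candidate with degree 8; its one candidate contact is binary-only,
  # so the not-complex flag holds; a second candidate pair shares a complex
  edges <- data.frame(
    a = c(rep("cand1", 8), "bait", "n1", "cand2", "cand2", "cand3"),
    b = c(paste0("n", 1:7), "cand2", "seed1", "seed1", "n2", "cand3", "n3"),
    has_binary = c(rep(TRUE, 12), FALSE),
    has_complex = c(rep(FALSE, 11), TRUE, TRUE))
  net <- build_network(edges)
  f <- candidate_network_features(net, c("cand1", "cand2", "cand3", "ghost"),
                                  bait = "bait", seeds = c("seed1", "seed2"))
  c1 <- f[f$id == "cand1", ]
  expect_equal(c1$degree, 8L)
  expect_true(c1$not_complex)            # candidate contact is binary-only
  expect_false(f$not_complex[f$id == "cand2"])  # complex with cand3
  expect_true(is.na(f$parkin_nd[f$id == "ghost"]))
  expect_true(is.na(f$not_complex[f$id == "ghost"]))

  # candidate adjacent to two seeds reports both as direct interactors
  net2 <- build_network(data.frame(a = c("c", "c"), b = c("s1", "s2")))
  expect_warning(
    f2 <- candidate_network_features(net2, "c", bait = "none",
                                     seeds = c("s1", "s2")),
    "no source protein")
  expect_equal(f2$seed_nd, 1)
  expect_equal(f2$seed_nd_count, 2L)
  expect_equal(f2$seed_interactors, "s1,s2")
})
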