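# corpus with p(A)=0.5, p(B)=0.25 on the root<-A<-B chain
chain_ic <- function() {
  dag <- chain_dag()
  ann <- chain_corpus(dag)
  list(dag = dag, ann = ann, ic = information_content(ann, dag))
}

test_that("information content follows corpus term probabilities", {
  fx <- chain_ic()
  expect_equal(unname(fx$ic$ic["root"]), 0)
  expect_equal(unname(fx$ic$ic["A"]), log(2), tolerance = 1e-12)
  expect_equal(unname(fx$ic$ic["B"]), log(4), tolerance = 1e-12)
})

test_that("term similarity matches the Lin and simRel formulas", {
  fx <- chain_ic()
  expect_equal(term_similarity("B", "B", fx$dag, fx$ic, "lin"), 1.0)
  # lin(A,B) = 2 IC(A) / (IC(A)+IC(B)) = 2 ln2 / (ln2 + ln4) = 2/3
  expect_equal(term_similarity("A", "B", fx$dag, fx$ic, "lin"), 2 / 3,
               tolerance = 1e-12)
  # simrel multiplies by 1 - p(MICA) = 1 - 0.5
  expect_equal(term_similarity("A", "B", fx$dag, fx$ic, "simrel"), 1 / 3,
               tolerance = 1e-12)
  # only common ancestor is the root -> 0
  expect_equal(term_similarity("root", "B", fx$dag, fx$ic, "lin"), 0)
  expect_error(term_similarity("ghost", "B", fx$dag, fx$ic),
               "information content")
})

test_that("protein similarity is the best-match average", {
  fx <- chain_ic()
  ann <- propagate_annotations(fx$dag, list(q1 = "A", q2 = c("A", "B"),
                                            q3 = "B", q4 = "A"))
  # hand-computed BMA for {A} vs {A,B}: (1 + (1 + 2/3)/2) / 2 = 11/12
  expect_equal(protein_funsim("q1", "q2", ann, fx$dag, fx$ic), 11 / 12,
               tolerance = 1e-12)
  # identical direct sets -> 1; symmetry
  expect_equal(protein_funsim("q1", "q4", ann, fx$dag, fx$ic), 1.0)
  expect_equal(protein_funsim("q1", "q2", ann, fx$dag, fx$ic),
               protein_funsim("q2", "q1", ann, fx$dag, fx$ic))
  # self-similarity 1 for any protein with a non-root direct term
  expect_equal(protein_funsim("q3", "q3", ann, fx$dag, fx$ic), 1.0)
})

test_that("disjoint branches under the root score zero", {
  dag <- load_ontology(write_obo_lines(c(
    "[Term]", "id: r", "name: r", "",
    "[Term]", "id: left", "name: l", "is_a: r ! r", "",
    "[Term]", "id: right", "name: g", "is_a: r ! r", "")))
  ann <- propagate_annotations(dag, list(p = "left", q = "right"))
  ic <- information_content(ann, dag)
  expect_equal(protein_funsim("p", "q", ann, dag, ic), 0)
})

test_that("adding a shared direct term never lowers similarity", {
  fx <- chain_ic()
  base <- propagate_annotations(fx$dag, list(p = "A", q = "B"))
  more <- propagate_annotations(fx$dag, list(p = c("A", "B"), q = c("B", "B")))
  s0 <- protein_funsim("p", "q", base, fx$dag, fx$ic)
  s1 <- protein_funsim("p", "q", more, fx$dag, fx$ic)
  expect_gte(s1, s0)
})

test_that("similarity network threshold is inclusive and keeps isolates", {
  sim <- matrix(c(1, 0.700, 0.699,
                  0.700, 1, 0.1,
                  0.699, 0.1, 1), 3, 3,
                dimnames = list(c("p", "q", "z"), c("p", "q", "z")))
  net <- build_funsim_network(sim, threshold = 0.7)
  e <- network_edges(net)
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e$a, e$b), c("p", "q"))
  expect_setequal(network_nodes(net), c("p", "q", "z"))  # isolate kept
})

test_that("funsim matrix is symmetric and order-invariant", {
  fx <- chain_ic()
  ann <- propagate_annotations(fx$dag, list(p1 = "A", p2 = c("B", "A"), p3 = "B"))
  m <- funsim_matrix(c("p1", "p2", "p3"), ann, fx$dag, fx$ic)
  expect_equal(m, t(m))
  m2 <- funsim_matrix(c("p3", "p1", "p2"), ann, fx$dag, fx$ic)
  expect_equal(m2["p1", "p2"], m["p1", "p2"])
  expect_warning(funsim_matrix(c("p1", "ghost"), ann, fx$dag, fx$ic),
                 "unannotated")
})

test_that("clustering separates cliques and unifies complete graphs", {
  # two 4-cliques joined by a single edge
  clique <- function(nodes) {
    cmb <- utils::combn(nodes, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  pairs <- rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4)),
                 data.frame(a = "a1", b = "b1"))
  net <- build_network(pairs)
  cl <- find_clusters(net, n_permutations = 49)
  expect_length(cl$clusters, 2L)
  got <- lapply(cl$clusters, sort)
  expect_true(any(vapply(got, identical, logical(1), paste0("a", 1:4))))
  expect_true(any(vapply(got, identical, logical(1), paste0("b", 1:4))))

  # complete graph collapses to one cluster holding every node
  k6 <- build_network(clique(paste0("k", 1:6)))
  cl6 <- find_clusters(k6, n_permutations = 9)
  expect_length(cl6$clusters, 1L)
  expect_setequal(cl6$clusters[[1]], paste0("k", 1:6))

  # graphs below the minimum size yield no clusters
  tiny <- build_network(data.frame(a = "x", b = "y"))
  expect_length(find_clusters(tiny)$clusters, 0L)
})

test_that("planted weighted modules are recovered as significant clusters", {
  set.seed(31)
  clique_w <- function(nodes, w) {
    cmb <- utils::combn(nodes, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ],
               weight = w + stats::runif(ncol(cmb), 0, 0.05))
  }
  mods <- lapply(1:4, function(i) paste0("m", i, "_", 1:6))
  pairs <- do.call(rbind, lapply(mods, clique_w, w = 0.85))
  bridges <- data.frame(a = c("m1_1", "m2_1", "m3_1", "m1_2"),
                        b = c("m2_2", "m3_2", "m4_2", "m4_1"),
                        weight = 0.72)
  g <- igraph::graph_from_data_frame(rbind(pairs, bridges), directed = FALSE)
  net <- structure(list(graph = g), class = "ppi_network")
  cl <- find_clusters(net, n_permutations = 199, seed = 17)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  recovered <- vapply(mods, function(m) {
    any(vapply(seq_along(cl$clusters), function(i) {
      jacc(cl$clusters[[i]], m) >= 0.8 && cl$significant[i]
    }, logical(1)))
  }, logical(1))
  expect_true(all(recovered))
})

test_that("clustering is deterministic under a fixed seed and locally maximal", {
  set.seed(8)
  pairs <- random_pairs(12, p_edge = 0.35)
  pairs$weight <- stats::runif(nrow(pairs), 0.5, 1)
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  net <- structure(list(graph = g), class = "ppi_network")
  a <- find_clusters(net, n_permutations = 49, seed = 17)
  b <- find_clusters(net, n_permutations = 49, seed = 17)
  expect_identical(a, b)
})

test_that("seed functional-similarity flags honour the threshold", {
  fx <- chain_ic()
  ann <- propagate_annotations(fx$dag, list(seed = "B", hit = "B",
                                            near = "A", far = "root"))
  fl <- funsim_seed_flags(c("hit", "near", "far", "ghost"), "seed",
                          ann, fx$dag, fx$ic, threshold = 0.7)
  expect_true(fl[["hit"]])      # identical rare term -> similarity 1
  expect_false(fl[["near"]])    # lin(A,B) = 2/3 < 0.7
  expect_false(fl[["ghost"]])   # unannotated
})
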