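test_that("hypergeometric tail matches hand-derived and boundary values", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1.0)
  # frozen from the exhaustive enumeration oracle: 5 of the 210 draws of 4
  # from 10 contain all 4 from the 5-element success class
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(6, 6, 6, 6), 1.0)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "k must be <= n")
  expect_error(hypergeom_upper_tail(2, 5, 3, 4), "n must be <= N")
})

test_that("hypergeometric tail equals exhaustive enumeration for all N <= 12", {
  for (N in 1:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        ks <- 0:min(n, K)
        got <- hypergeom_upper_tail(ks, n, K, N)
        want <- enum_hypergeom_tails(n, K, N)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("one-sided Fisher 2x2 equals the hypergeometric tail", {
  set.seed(9)
  for (rep in 1:50) {
    N <- sample(10:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    m <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(hypergeom_upper_tail(k, n, K, N),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("classic enrichment ranks the planted term first and applies BH", {
  dag <- load_ontology(write_obo_lines(c(
    "[Term]", "id: r", "name: r", "",
    "[Term]", "id: t", "name: t", "is_a: r ! r", "",
    "[Term]", "id: u", "name: u", "is_a: r ! r", "")))
  direct <- c(lapply(stats::setNames(nm = sprintf("a%02d", 1:10)), function(.) "t"),
              lapply(stats::setNames(nm = sprintf("b%02d", 1:10)), function(.) "u"))
  ann <- propagate_annotations(dag, direct)
  res <- classic_enrichment(sprintf("a%02d", 1:10), ann, dag)
  expect_equal(res$term_id[1], "t")
  expect_true(all(res$classic_fdr >= res$classic_p))
  expect_warning(classic_enrichment(character(0), ann, dag), "empty study")
})

test_that("BH adjustment matches hand-computed values and is monotone", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(4)
  for (rep in 1:20) {
    p <- sort(stats::runif(sample(3:12, 1)))
    adj <- stats::p.adjust(p, method = "BH")
    expect_true(all(diff(adj) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("null studies are calibrated at the nominal type-I level", {
  # single balanced term, large counts: the discrete tail is near-uniform;
  # draw the null overlap directly from the hypergeometric null
  set.seed(123)
  N <- 1000; K <- 500; n <- 100
  k <- stats::rhyper(1000, K, N - K, n)
  frac <- mean(hypergeom_upper_tail(k, n, K, N) <= 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

elim_fixture <- function() {
  dag <- load_ontology(write_obo_lines(c(
    "[Term]", "id: r", "name: r", "",
    "[Term]", "id: parent", "name: p", "is_a: r ! r", "",
    "[Term]", "id: leaf", "name: l", "is_a: parent ! p", "",
    "[Term]", "id: lone", "name: x", "is_a: r ! r", "")))
  # every study protein annotated to the leaf; the parent has no signal of
  # its own beyond what the leaf explains
  direct <- c(lapply(stats::setNames(nm = sprintf("s%02d", 1:8)), function(.) "leaf"),
              lapply(stats::setNames(nm = sprintf("n%02d", 1:24)), function(.) "lone"))
  list(dag = dag, ann = propagate_annotations(dag, direct),
       study = sprintf("s%02d", 1:8))
}

test_that("elim-style adjustment removes signal explained by descendants", {
  fx <- elim_fixture()
  cls <- classic_enrichment(fx$study, fx$ann, fx$dag)
  loc <- local_adjusted_enrichment(fx$study, fx$ann, fx$dag, cutoff = 0.01)
  leaf_cls <- cls$classic_p[cls$term_id == "leaf"]
  par_cls <- cls$classic_p[cls$term_id == "parent"]
  leaf_loc <- loc$local_p[loc$term_id == "leaf"]
  par_loc <- loc$local_p[loc$term_id == "parent"]
  expect_equal(leaf_loc, leaf_cls)           # leaf tested untouched
  expect_gt(par_loc, par_cls * 100)          # parent signal stripped away
})

test_that("local adjustment is inert on independent branches and at cutoff 0", {
  dag <- load_ontology(write_obo_lines(c(
    "[Term]", "id: r", "name: r", "",
    "[Term]", "id: b1", "name: b1", "is_a: r ! r", "",
    "[Term]", "id: b2", "name: b2", "is_a: r ! r", "")))
  direct <- c(lapply(stats::setNames(nm = sprintf("s%d", 1:5)), function(.) "b1"),
              lapply(stats::setNames(nm = sprintf("n%d", 1:5)), function(.) "b2"))
  ann <- propagate_annotations(dag, direct)
  study <- sprintf("s%d", 1:5)
  cls <- classic_enrichment(study, ann, dag)
  loc <- local_adjusted_enrichment(study, ann, dag, cutoff = 0.01)
  shared <- setdiff(intersect(cls$term_id, loc$term_id), "r")
  expect_equal(loc$local_p[match(shared, loc$term_id)],
               cls$classic_p[match(shared, cls$term_id)])

  fx <- elim_fixture()
  loc0 <- local_adjusted_enrichment(fx$study, fx$ann, fx$dag, cutoff = 0)
  cls0 <- classic_enrichment(fx$study, fx$ann, fx$dag)
  expect_equal(loc0$local_p[match(cls0$term_id, loc0$term_id)],
               cls0$classic_p)
})

test_that("shared-term flags OR descendant annotation over comparison terms", {
  dag <- load_ontology(write_obo_lines(c(
    "[Term]", "id: r", "name: r", "",
    "[Term]", "id: comp", "name: c", "is_a: r ! r", "",
    "[Term]", "id: compchild", "name: cc", "is_a: comp ! c", "",
    "[Term]", "id: other", "name: o", "is_a: r ! r", "")))
  ann <- propagate_annotations(dag, list(c1 = "compchild", c2 = "other",
                                         c3 = "comp"))
  fl <- shared_term_flags(NULL, NULL, dag, ann, c("c1", "c2", "c3", "c4"),
                          comparison_terms = "comp")
  expect_true(fl$flags$gocomp[fl$flags$id == "c1"])   # via descendant
  expect_true(fl$flags$gocomp[fl$flags$id == "c3"])
  expect_false(fl$flags$gocomp[fl$flags$id == "c2"])
  expect_false(fl$flags$gocomp[fl$flags$id == "c4"])  # unannotated

  # dual-significance derivation path
  res_a <- data.frame(term_id = c("comp", "other"), classic_p = c(1e-5, 0.5))
  res_b <- data.frame(term_id = c("comp", "other"), classic_p = c(1e-4, 1e-6))
  fl2 <- shared_term_flags(res_a, res_b, dag, ann, "c1", cutoff = 1e-3)
  expect_equal(fl2$terms, "comp")
  expect_true(fl2$flags$gocomp)
})

test_that("flat pathway enrichment works over GMT-like collections", {
  path <- write_tsv_lines(c("setA\tdesc\tp1\tp2\tp3",
                            "setB\tdesc\tp4\tp5\tp6\tp7"))
  coll <- read_gene_set_collection(path)
  expect_length(coll, 2L)
  res <- pathway_enrichment(c("p1", "p2", "p3"), coll)
  expect_equal(res$set_name[1], "setA")
  expect_lt(res$classic_p[1], res$classic_p[2])
})
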