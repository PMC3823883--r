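# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# Exhaustive hypergeometric tail: enumerate every possible draw of n from N
# (successes are elements 1..K) and count draws with >= k successes.
enum_hypergeom_tail <- function(k, n, K, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  succ <- if (K == 0L) rep(0L, ncol(draws)) else colSums(draws <= K)
  sum(succ >= k) / ncol(draws)
}

# Full distribution variant: tail probabilities for every k in 0..min(n,K)
enum_hypergeom_tails <- function(n, K, N) {
  ks <- 0:min(n, K)
  vapply(ks, enum_hypergeom_tail, numeric(1), n = n, K = K, N = N)
}

# Floyd-Warshall all-pairs shortest paths on an unweighted edge list
fw_distances <- function(nodes, edges_a, edges_b) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_along(edges_a)) {
    a <- edges_a[i]; b <- edges_b[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (m in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  d
}

# random simple graph as a pair table (connected not guaranteed)
random_pairs <- function(n_nodes, p_edge = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  cmb <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(cmb)) < p_edge
  data.frame(a = cmb[1L, keep], b = cmb[2L, keep], stringsAsFactors = FALSE)
}

# Chain ontology root <- A <- B written as an in-memory go_dag via OBO text
chain_dag <- function() {
  load_ontology(write_obo_lines(c(
    "[Term]", "id: root", "name: root", "namespace: biological_process", "",
    "[Term]", "id: A", "name: mid", "namespace: biological_process",
    "is_a: root ! root", "",
    "[Term]", "id: B", "name: leaf", "namespace: biological_process",
    "is_a: A ! mid", "")))
}

write_obo_lines <- function(body) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", body), path)
  path
}

# corpus on the chain with p(A)=0.5, p(B)=0.25: 4 proteins, 2 direct to A
# (one of them via B), 1 more elsewhere-rooted
chain_corpus <- function(dag) {
  propagate_annotations(dag, list(p1 = "B", p2 = "A", p3 = "root", p4 = "root"))
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
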