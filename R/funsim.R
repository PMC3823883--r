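#' Information content of ontology terms
#'
#' IC(t) = -ln p(t), where p(t) is the fraction of annotated proteins in the
#' corpus annotated (after propagation) to t or any descendant. The root of
#' the namespace therefore has IC 0; terms annotating nothing have no
#' defined IC and are excluded.
#'
#' @param annotations An `annotation_set` (the corpus).
#' @param dag A `go_dag`.
#' @return List with `ic` and `p` (named numeric vectors over terms with at
#'   least one propagated annotation).
#' @export
information_content <- function(annotations, dag) {
  n_total <- length(annotations$propagated)
  if (n_total == 0L) stop("no annotated proteins in corpus")
  counts <- lengths(annotations$term_proteins)
  p <- counts / n_total
  list(ic = -log(p), p = p)
}

#' Semantic similarity between two ontology terms
#'
#' Scores the similarity of two terms through their most informative common
#' ancestor (MICA). `lin` = 2 IC(MICA) / (IC(t1) + IC(t2)); `simrel`
#' multiplies the Lin score by (1 - p(MICA)), down-weighting similarity
#' through shallow (common) ancestors. Both lie in `[0, 1]`; terms whose
#' only common ancestor is the root score 0.
#'
#' @param t1,t2 Term ids (must have defined IC).
#' @param dag A `go_dag`.
#' @param ic Output of [information_content()].
#' @param kernel `"lin"` or `"simrel"`.
#' @return Similarity score.
#' @export
term_similarity <- function(t1, t2, dag, ic, kernel = c("lin", "simrel")) {
  kernel <- match.arg(kernel)
  if (!(t1 %in% names(ic$ic)) || !(t2 %in% names(ic$ic))) {
    stop("term without defined information content")
  }
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  common <- intersect(common, names(ic$ic))
  if (length(common) == 0L) return(0)
  mica <- common[which.max(ic$ic[common])]
  denom <- ic$ic[[t1]] + ic$ic[[t2]]
  if (denom <= 0) return(0)            # both terms are root-probability terms
  lin <- 2 * ic$ic[[mica]] / denom
  if (kernel == "lin") lin else lin * (1 - ic$p[[mica]])
}

#' Functional similarity between two proteins (best-match average)
#'
#' Builds the matrix of pairwise term similarities over the two proteins'
#' direct annotation sets (restricted to terms with defined IC) and returns
#' the best-match average: the mean of the average row maxima and average
#' column maxima. For proteins carrying several identifier variants, the
#' conventional score is the maximum over variants; pass each variant's
#' annotation and take `max()` externally, or use the annotation union.
#'
#' @param p1,p2 Protein ids.
#' @param annotations An `annotation_set`.
#' @param dag A `go_dag`.
#' @param ic Output of [information_content()].
#' @param kernel `"lin"` or `"simrel"`.
#' @return Score in `[0, 1]`, or `NA` if either protein has no scorable
#'   annotation.
#' @export
protein_funsim <- function(p1, p2, annotations, dag, ic,
                           kernel = c("lin", "simrel")) {
  kernel <- match.arg(kernel)
  ts1 <- intersect(annotations$direct[[p1]], names(ic$ic))
  ts2 <- intersect(annotations$direct[[p2]], names(ic$ic))
  if (length(ts1) == 0L || length(ts2) == 0L) return(NA_real_)
  m <- outer(ts1, ts2, Vectorize(function(a, b) {
    term_similarity(a, b, dag, ic, kernel)
  }))
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' All-pairs functional similarity matrix
#'
#' @param proteins Character vector of protein ids; unannotated proteins are
#'   dropped with a warning.
#' @inheritParams protein_funsim
#' @return Symmetric numeric matrix with protein ids as dimnames.
#' @export
funsim_matrix <- function(proteins, annotations, dag, ic,
                          kernel = c("lin", "simrel")) {
  kernel <- match.arg(kernel)
  annotated <- proteins[proteins %in% names(annotations$direct)]
  if (length(annotated) < length(proteins)) {
    warning(length(proteins) - length(annotated),
            " unannotated protein(s) excluded from similarity matrix")
  }
  n <- length(annotated)
  m <- matrix(NA_real_, n, n, dimnames = list(annotated, annotated))
  # cache term-level similarities: proteins share few distinct terms
  term_cache <- new.env(parent = emptyenv())
  tsim <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    v <- term_cache[[key]]
    if (is.null(v)) {
      v <- term_similarity(a, b, dag, ic, kernel)
      term_cache[[key]] <- v
    }
    v
  }
  direct <- lapply(annotated, function(p) intersect(annotations$direct[[p]], names(ic$ic)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ts1 <- direct[[i]]; ts2 <- direct[[j]]
      if (length(ts1) == 0L || length(ts2) == 0L) next
      sm <- outer(ts1, ts2, Vectorize(tsim))
      s <- (mean(apply(sm, 1L, max)) + mean(apply(sm, 2L, max))) / 2
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Build a functional-similarity network at a threshold
#'
#' Connects two proteins iff their similarity score is at or above the
#' threshold (inclusive). Edge weights carry the score; proteins scoring
#' below threshold against everything are retained as isolated nodes.
#'
#' @param sim Symmetric similarity matrix (as from [funsim_matrix()]).
#' @param threshold Edge threshold (default 0.7).
#' @return A `ppi_network` whose graph has a numeric `weight` edge
#'   attribute.
#' @export
build_funsim_network <- function(sim, threshold = 0.7) {
  ids <- rownames(sim)
  idx <- which(upper.tri(sim) & !is.na(sim) & sim >= threshold, arr.ind = TRUE)
  edges <- data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]],
                      weight = sim[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  structure(list(graph = g), class = "ppi_network")
}

#' Overlapping cluster detection by greedy cohesiveness growth
#'
#' Identifies densely connected, possibly overlapping regions of a weighted
#' graph. Cluster quality is the cohesiveness
#' f(C) = w_in / (w_in + w_bound + penalty * |C|), where w_in is the total
#' edge weight inside C and w_bound the total weight of edges crossing the
#' boundary. Clusters are seeded from the highest-weighted-degree node not
#' yet claimed by a cluster and grown/shrunk greedily until f is locally
#' maximal; clusters with match coefficient |A∩B|^2/(|A||B|) at or above
#' `overlap_merge` are merged. Cluster significance is assessed empirically
#' by permuting the edge weights over the fixed topology (degree-preserving)
#' and recomputing f for the same node set.
#'
#' @param net Weighted `ppi_network` (missing weights default to 1).
#' @param min_size Minimum cluster size (default 3).
#' @param penalty Cohesiveness node penalty (default 2).
#' @param overlap_merge Match-coefficient merge threshold (default 0.8).
#' @param n_permutations Number of weight permutations for the empirical p
#'   (default 1000).
#' @param p_cutoff Significance threshold (default 0.05).
#' @param seed RNG seed for the permutations (default 17).
#' @return List with `clusters` (list of node-id vectors), `quality`
#'   (cohesiveness per cluster), `p` (empirical p per cluster) and
#'   `significant` (logical).
#' @export
find_clusters <- function(net, min_size = 3, penalty = 2, overlap_merge = 0.8,
                          n_permutations = 1000, p_cutoff = 0.05, seed = 17) {
  g <- net$graph
  if (igraph::vcount(g) < min_size) {
    return(list(clusters = list(), quality = numeric(0), p = numeric(0),
                significant = logical(0)))
  }
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- weighted_adjacency(g, w)

  cohesiveness <- function(members, A = adj) {
    inside <- A[members, members, drop = FALSE]
    w_in <- sum(inside) / 2
    w_tot <- sum(A[members, , drop = FALSE])   # 2*w_in + w_bound
    w_bound <- w_tot - 2 * w_in
    denom <- w_in + w_bound + penalty * length(members)
    if (denom <= 0) 0 else w_in / denom
  }

  wdeg <- rowSums(adj)
  claimed <- stats::setNames(rep(FALSE, n), nodes)
  clusters <- list()
  for (v in nodes[order(-wdeg, nodes)]) {
    if (claimed[[v]]) next
    if (wdeg[[v]] <= 0) next
    C <- v
    f <- cohesiveness(C)
    repeat {
      boundary <- setdiff(nodes[colSums(adj[C, , drop = FALSE]) > 0], C)
      cand_add <- vapply(boundary, function(u) cohesiveness(c(C, u)), numeric(1))
      cand_rm <- if (length(C) > 1L) {
        vapply(C, function(u) cohesiveness(setdiff(C, u)), numeric(1))
      } else numeric(0)
      best_add <- if (length(cand_add)) max(cand_add) else -Inf
      best_rm <- if (length(cand_rm)) max(cand_rm) else -Inf
      if (max(best_add, best_rm) <= f + 1e-12) break
      if (best_add >= best_rm) {
        pick <- boundary[which.max(cand_add)]
        C <- c(C, pick)
        f <- best_add
      } else {
        pick <- C[which.max(cand_rm)]
        C <- setdiff(C, pick)
        f <- best_rm
      }
    }
    claimed[C] <- TRUE
    if (length(C) >= min_size) clusters[[length(clusters) + 1L]] <- sort(C)
  }

  # merge heavily overlapping clusters (match coefficient)
  merged <- TRUE
  while (merged && length(clusters) > 1L) {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        ov <- length(intersect(clusters[[i]], clusters[[j]]))
        mc <- ov^2 / (length(clusters[[i]]) * length(clusters[[j]]))
        if (mc >= overlap_merge) {
          clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }

  quality <- vapply(clusters, cohesiveness, numeric(1))

  # empirical significance: permute edge weights over fixed topology
  p <- rep(NA_real_, length(clusters))
  if (length(clusters)) {
    set.seed(seed)
    ge <- igraph::as_data_frame(g, what = "edges")
    exceed <- integer(length(clusters))
    for (b in seq_len(n_permutations)) {
      wp <- sample(w)
      Ap <- matrix(0, n, n, dimnames = list(nodes, nodes))
      Ap[cbind(ge$from, ge$to)] <- wp
      Ap[cbind(ge$to, ge$from)] <- wp
      for (ci in seq_along(clusters)) {
        if (cohesiveness(clusters[[ci]], Ap) >= quality[ci]) {
          exceed[ci] <- exceed[ci] + 1L
        }
      }
    }
    p <- (exceed + 1) / (n_permutations + 1)
  }
  list(clusters = clusters, quality = quality, p = p,
       significant = p <= p_cutoff)
}

weighted_adjacency <- function(g, w) {
  nodes <- igraph::V(g)$name
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ge <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ge)) {
    A[cbind(ge$from, ge$to)] <- w
    A[cbind(ge$to, ge$from)] <- w
  }
  A
}

#' Per-candidate functional-similarity flag against a seed set
#'
#' TRUE iff the candidate's best functional similarity to any seed protein
#' reaches the threshold (the "functionally similar to a disease protein"
#' feature of the prioritization tree).
#'
#' @param candidates,seeds Character vectors of protein ids.
#' @inheritParams protein_funsim
#' @param threshold Similarity threshold (default 0.7).
#' @return Named logical vector over candidates (FALSE when unannotated).
#' @export
funsim_seed_flags <- function(candidates, seeds, annotations, dag, ic,
                              kernel = "lin", threshold = 0.7) {
  seeds <- seeds[seeds %in% names(annotations$direct)]
  out <- vapply(candidates, function(p) {
    if (!p %in% names(annotations$direct) || length(seeds) == 0L) return(FALSE)
    s <- vapply(seeds, function(q) protein_funsim(p, q, annotations, dag, ic, kernel),
                numeric(1))
    any(!is.na(s) & s >= threshold)
  }, logical(1))
  names(out) <- candidates
  out
}
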