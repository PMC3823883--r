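#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric drawing `n` from a population of `N`
#' containing `K` successes. This is the one-sided Fisher exact test on the
#' corresponding 2x2 table, and the standard over-representation score for
#' gene-set enrichment. Computed via `stats::phyper` (log-space internals),
#' vectorized over all arguments.
#'
#' @param k Observed successes in the sample (study hits in the set).
#' @param n Sample (study) size.
#' @param K Successes in the population (population hits in the set).
#' @param N Population (universe) size.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("negative argument")
  if (any(k > n)) stop("k must be <= n")
  if (any(n > N)) stop("n must be <= N")
  if (any(K > N)) stop("K must be <= N")
  if (any(k > K)) stop("k must be <= K")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Classic gene-set enrichment over an ontology
#'
#' For every term annotating at least one universe protein (propagated
#' annotations), tests over-representation of the study set by the
#' hypergeometric upper tail ("classic" score) and adjusts across all tested
#' terms by Benjamini-Hochberg FDR. Term dependencies in the DAG are
#' deliberately ignored here; see [local_adjusted_enrichment()] for the
#' topology-aware variant.
#'
#' @param study Character vector of study protein ids (must be contained in
#'   the universe).
#' @param annotations An `annotation_set`.
#' @param dag A `go_dag` (used only to attach term names).
#' @param universe Character vector of universe protein ids; defaults to all
#'   annotated proteins in `annotations`.
#' @return `data.frame` with columns `term_id`, `name`, `k`, `n`, `K`, `N`,
#'   `classic_p`, `classic_fdr`, sorted by `classic_p`.
#' @export
classic_enrichment <- function(study, annotations, dag = NULL, universe = NULL) {
  if (is.null(universe)) universe <- names(annotations$propagated)
  study <- intersect(unique(study), universe)
  if (length(study) == 0L) {
    warning("empty study set (after restriction to universe)")
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), classic_p = numeric(0),
                      classic_fdr = numeric(0)))
  }
  tp <- lapply(annotations$term_proteins, intersect, universe)
  tp <- tp[lengths(tp) > 0L]
  N <- length(universe); n <- length(study)
  K <- lengths(tp)
  k <- vapply(tp, function(ps) length(intersect(ps, study)), integer(1))
  p <- hypergeom_upper_tail(k, n, K, N)
  out <- data.frame(term_id = names(tp), k = unname(k), n = n, K = unname(K),
                    N = N, classic_p = unname(p),
                    classic_fdr = unname(stats::p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out$name <- if (!is.null(dag)) dag$terms$name[match(out$term_id, dag$terms$id)] else ""
  out <- out[order(out$classic_p, out$term_id),
             c("term_id", "name", "k", "n", "K", "N", "classic_p", "classic_fdr")]
  rownames(out) <- NULL
  out
}

#' Locally adjusted (elim-style) enrichment
#'
#' Topology-aware enrichment that down-weights generic terms relative to
#' their more specific descendants. Terms are processed from the most
#' specific (greatest depth) upward; when a term's p-value at its test time
#' is at or below `cutoff`, the universe proteins annotated to it are
#' removed from all of its ancestors before those are tested, so an
#' ancestor is only called significant on signal its significant descendants
#' do not already explain. With `cutoff = 0` nothing is ever removed and the
#' local p equals the classic p for every term.
#'
#' @inheritParams classic_enrichment
#' @param cutoff Significance threshold triggering removal (default 0.01).
#' @return `data.frame` with columns `term_id`, `name`, `k`, `K`, `n`, `N`,
#'   `local_p` (the p-value each term obtained at its test time), sorted by
#'   `local_p`.
#' @export
local_adjusted_enrichment <- function(study, annotations, dag,
                                      universe = NULL, cutoff = 0.01) {
  if (is.null(universe)) universe <- names(annotations$propagated)
  study <- intersect(unique(study), universe)
  if (length(study) == 0L) {
    warning("empty study set (after restriction to universe)")
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), local_p = numeric(0)))
  }
  tp <- lapply(annotations$term_proteins, intersect, universe)
  tp <- tp[lengths(tp) > 0L]
  term_ids <- names(tp)
  depth <- term_depths(dag)
  ord <- term_ids[order(-depth[term_ids], term_ids)]   # deepest first, stable

  N <- length(universe); n <- length(study)
  res <- vector("list", length(ord))
  anc_cache <- ancestor_closure(dag)
  for (i in seq_along(ord)) {
    t <- ord[i]
    ps <- tp[[t]]
    K <- length(ps)
    k <- length(intersect(ps, study))
    p <- if (K == 0L) 1.0 else hypergeom_upper_tail(k, n, K, N)
    res[[i]] <- data.frame(term_id = t, k = k, K = K, n = n, N = N,
                           local_p = p, stringsAsFactors = FALSE)
    if (p <= cutoff && K > 0L) {
      ancs <- setdiff(intersect(anc_cache[[t]], names(tp)), t)
      for (a in ancs) tp[[a]] <- setdiff(tp[[a]], ps)
    }
  }
  out <- do.call(rbind, res)
  out$name <- dag$terms$name[match(out$term_id, dag$terms$id)]
  out <- out[order(out$local_p, out$term_id),
             c("term_id", "name", "k", "K", "n", "N", "local_p")]
  rownames(out) <- NULL
  out
}

# depth of each term = length of the longest path to a root (roots at 0)
term_depths <- function(dag) {
  ord <- rev(topological_order(dag))  # roots first
  depth <- stats::setNames(integer(length(ord)), ord)
  for (t in ord) {
    ps <- dag$parents[[t]]
    depth[[t]] <- if (length(ps)) max(depth[ps]) + 1L else 0L
  }
  depth
}

#' Shared-term annotation flags (GO-comparison flags)
#'
#' Given enrichment results for two datasets (e.g. the screen candidates and
#' the disease-related reference set), identifies the comparison terms —
#' terms significant at `cutoff` (classic p) in *both* — optionally extended
#' by an explicit list (e.g. terms selected by the locally adjusted score).
#' Each candidate is then flagged per comparison term if it is directly
#' annotated to the term or to any descendant, and an overall flag is the OR
#' over the comparison terms.
#'
#' @param results_a,results_b Enrichment tables from [classic_enrichment()]
#'   over the same DAG.
#' @param dag A `go_dag`.
#' @param annotations An `annotation_set`.
#' @param candidates Character vector of candidate protein ids.
#' @param cutoff Classic-p threshold for dual significance (default 1e-3).
#' @param comparison_terms Optional explicit term ids; if supplied they are
#'   used as-is (the dual-significance derivation is skipped).
#' @param extra_terms Term ids appended to the derived dual-significant list.
#' @return List with `terms` (the comparison term ids) and `flags`
#'   (`data.frame`: `id`, one logical column per comparison term, and
#'   `gocomp` = OR over them).
#' @export
shared_term_flags <- function(results_a, results_b, dag, annotations,
                              candidates, cutoff = 1e-3,
                              comparison_terms = NULL,
                              extra_terms = character(0)) {
  if (is.null(comparison_terms)) {
    sig_a <- results_a$term_id[results_a$classic_p <= cutoff]
    sig_b <- results_b$term_id[results_b$classic_p <= cutoff]
    comparison_terms <- union(intersect(sig_a, sig_b), extra_terms)
  }
  comparison_terms <- intersect(comparison_terms, dag$terms$id)
  flags <- data.frame(id = candidates, stringsAsFactors = FALSE)
  for (t in comparison_terms) {
    down <- term_descendants(dag, t, include_self = TRUE)
    flags[[t]] <- vapply(candidates, function(p) {
      d <- annotations$direct[[p]]
      !is.null(d) && length(intersect(d, down)) > 0L
    }, logical(1))
  }
  flags$gocomp <- if (length(comparison_terms)) {
    as.logical(apply(flags[, comparison_terms, drop = FALSE], 1L, any))
  } else rep(FALSE, length(candidates))
  list(terms = comparison_terms, flags = flags)
}

#' Read a flat gene-set collection (GMT-like)
#'
#' `set_name TAB description TAB member TAB member ...`; no header, `#`
#' comments skipped. Used for pathway over-representation analysis where no
#' DAG structure applies.
#'
#' @param path Path to the GMT-like file.
#' @return Named list of character member vectors; descriptions as the
#'   `"description"` attribute.
#' @export
read_gene_set_collection <- function(path) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 3L
  fields <- fields[ok]
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Pathway over-representation analysis over a flat collection
#'
#' Classic hypergeometric enrichment of a study set against each gene set in
#' a flat collection (no ontology structure), BH-adjusted.
#'
#' @param study Character vector of study ids.
#' @param collection Named list of gene sets (see
#'   [read_gene_set_collection()]).
#' @param universe Character vector of universe ids; defaults to the union
#'   of all collection members.
#' @return `data.frame` with `set_name`, `k`, `n`, `K`, `N`, `classic_p`,
#'   `classic_fdr`, sorted by `classic_p`.
#' @export
pathway_enrichment <- function(study, collection, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(collection, use.names = FALSE))
  study <- intersect(unique(study), universe)
  sets <- lapply(collection, intersect, universe)
  K <- lengths(sets)
  keep <- K > 0L
  sets <- sets[keep]; K <- K[keep]
  N <- length(universe); n <- length(study)
  k <- vapply(sets, function(s) length(intersect(s, study)), integer(1))
  p <- hypergeom_upper_tail(k, n, K, N)
  out <- data.frame(set_name = names(sets), k = unname(k), n = n,
                    K = unname(K), N = N, classic_p = unname(p),
                    classic_fdr = unname(stats::p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$classic_p, out$set_name), ]
  rownames(out) <- NULL
  out
}
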