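#' Load an ontology DAG from an OBO 1.2 flat file
#'
#' Minimal OBO reader covering the fields this package needs: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a` and `is_obsolete`.
#' Obsolete terms are skipped; only `is_a` edges are retained. The result is
#' validated to be acyclic (a cycle is a fatal format error). `is_a` targets
#' referring to terms absent from the file are dropped.
#'
#' @param path Path to the OBO file.
#' @return A `go_dag`: list with `terms` (`data.frame`: `id`, `name`,
#'   `namespace`), `parents` and `children` (named lists id -> character
#'   vector), and `roots` (ids with no parent).
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <<- cur
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(parents = character(0)); in_term <- TRUE
    } else if (startsWith(ln, "[")) {     # [Typedef] etc.
      flush(cur); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: *", "", ln)
      else if (startsWith(ln, "name: ")) cur$name <- sub("^name: *", "", ln)
      else if (startsWith(ln, "namespace: ")) cur$namespace <- sub("^namespace: *", "", ln)
      else if (startsWith(ln, "is_a: ")) {
        tgt <- sub("^is_a: *", "", ln)
        tgt <- trimws(sub("!.*$", "", tgt))
        cur$parents <- c(cur$parents, tgt)
      } else if (startsWith(ln, "is_obsolete: true")) cur$obsolete <- TRUE
    }
  }
  flush(cur)
  if (length(terms) == 0L) stop("no terms parsed from ", path)

  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(unique(t$parents), ids))
  names(parents) <- ids
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  dag <- structure(list(
    terms = data.frame(
      id = ids,
      name = vapply(terms, function(t) t$name %||% "", character(1)),
      namespace = vapply(terms, function(t) t$namespace %||% "", character(1)),
      stringsAsFactors = FALSE, row.names = NULL),
    parents = parents,
    children = children,
    roots = ids[lengths(parents) == 0L]), class = "go_dag")
  if (is.null(topological_order(dag))) stop("cycle detected in ontology ", path)
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", nrow(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

# Kahn topological order (children before parents); NULL if cyclic
topological_order <- function(dag) {
  ids <- dag$terms$id
  n_unvisited_children <- lengths(dag$children)
  queue <- ids[n_unvisited_children == 0L]      # leaves first
  order <- character(0)
  counts <- n_unvisited_children
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (p in dag$parents[[v]]) {
      counts[[p]] <- counts[[p]] - 1L
      if (counts[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) != length(ids)) NULL else order
}

#' Ancestors of an ontology term
#' @param dag A `go_dag`.
#' @param term Term id (must exist).
#' @param include_self Include the term itself (default TRUE).
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term, include_self = TRUE) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  seen <- unique(seen)
  if (include_self) seen else setdiff(seen, term)
}

#' Descendants of an ontology term
#' @inheritParams term_ancestors
#' @return Character vector of descendant term ids.
#' @export
term_descendants <- function(dag, term, include_self = TRUE) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(dag$children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  seen <- unique(seen)
  if (include_self) seen else setdiff(seen, term)
}

#' Read protein annotations from a GAF-like table
#'
#' Two- or three-column TSV: `protein_id TAB term_id [TAB evidence]`, no
#' header, `#` comments skipped. Evidence codes are carried through but not
#' filtered on.
#'
#' @param path Path to the annotation file.
#' @return `data.frame` with columns `protein_id`, `term_id`, `evidence`.
#' @export
read_annotations <- function(path) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 2L
  data.frame(
    protein_id = vapply(fields[ok], `[[`, character(1), 1L),
    term_id = vapply(fields[ok], `[[`, character(1), 2L),
    evidence = vapply(fields[ok], function(f) if (length(f) >= 3L) f[[3L]] else "",
                      character(1)),
    stringsAsFactors = FALSE)
}

#' Propagate direct annotations up the ontology
#'
#' The true-path rule: a protein annotated to a term is implicitly annotated
#' to every ancestor of that term. Annotations to terms absent from the DAG
#' are dropped with a warning.
#'
#' @param dag A `go_dag`.
#' @param direct Either a `data.frame` with columns `protein_id`/`term_id`
#'   (as from [read_annotations()]) or a named list protein -> term ids.
#' @return An `annotation_set`: list with `direct` and `propagated` (named
#'   lists protein -> term id vectors) plus `term_proteins` (propagated
#'   reverse index term -> protein ids).
#' @export
propagate_annotations <- function(dag, direct) {
  if (is.data.frame(direct)) {
    direct <- lapply(split(direct$term_id, direct$protein_id), unique)
  }
  known <- dag$terms$id
  dropped <- 0L
  direct <- lapply(direct, function(ts) {
    keep <- ts %in% known
    dropped <<- dropped + sum(!keep)
    unique(ts[keep])
  })
  if (dropped > 0L) warning(dropped, " annotation(s) to unknown terms dropped")
  direct <- direct[lengths(direct) > 0L]

  anc_cache <- ancestor_closure(dag)
  propagated <- lapply(direct, function(ts) {
    unique(unlist(anc_cache[ts], use.names = FALSE))
  })
  term_proteins <- invert_annotation(propagated)
  structure(list(direct = direct, propagated = propagated,
                 term_proteins = term_proteins),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$direct), "proteins,",
      length(x$term_proteins), "terms with >=1 propagated annotation\n")
  invisible(x)
}

# full ancestor closure (incl self) for all terms, computed once via
# topological order (children before parents is the wrong direction here;
# we need parents resolved before children, i.e. reversed order)
ancestor_closure <- function(dag) {
  ord <- rev(topological_order(dag))  # roots first
  cache <- stats::setNames(vector("list", length(ord)), ord)
  for (t in ord) {
    ps <- dag$parents[[t]]
    cache[[t]] <- unique(c(t, unlist(cache[ps], use.names = FALSE)))
  }
  cache
}

invert_annotation <- function(prot_to_terms) {
  if (length(prot_to_terms) == 0L) return(list())
  prots <- rep(names(prot_to_terms), lengths(prot_to_terms))
  terms <- unlist(prot_to_terms, use.names = FALSE)
  lapply(split(prots, terms), unique)
}

#' GO slim membership flags
#'
#' A protein belongs to the slim iff at least one of its *direct*
#' annotations falls inside the slim or any descendant of a slim term
#' (equivalently: its propagated annotations intersect the slim itself).
#'
#' @param annotations An `annotation_set`.
#' @param slim Character vector of slim term ids (must be in the DAG).
#' @param dag A `go_dag`.
#' @param proteins Optional protein ids to report on (default: all annotated).
#' @return Named logical vector, one entry per protein.
#' @export
slim_membership <- function(annotations, slim, dag,
                            proteins = names(annotations$direct)) {
  missing <- setdiff(slim, dag$terms$id)
  if (length(missing)) stop("slim term(s) not in DAG: ", paste(missing, collapse = ", "))
  slim_down <- unique(unlist(lapply(slim, term_descendants, dag = dag,
                                    include_self = TRUE)))
  out <- vapply(proteins, function(p) {
    d <- annotations$direct[[p]]
    !is.null(d) && length(intersect(d, slim_down)) > 0L
  }, logical(1))
  names(out) <- proteins
  out
}
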