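#' Read interaction records from a MITAB-like table
#'
#' Expects a tab-delimited file with columns
#' `record_id, member_ids (';'-separated), kind (binary|complex),
#' detection_method, source`; no header, `#` comments skipped. Records with
#' fewer than two members are dropped with a warning. A record declared
#' `complex` with exactly two members is demoted to `binary` (logged via
#' warning): a two-member "complex" carries no more than pairwise evidence.
#'
#' @param path Path to the interaction file.
#' @return `data.frame` with columns `record_id`, `members` (list column of
#'   character vectors, order preserved), `kind`, `detection_method`,
#'   `source`.
#' @export
read_interactions <- function(path) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 5L)) {
    stop("interaction file ", path, ": malformed line ", which(ncol < 5L)[1],
         " (expected 5 tab-delimited columns)")
  }
  members <- lapply(fields, function(f) strsplit(f[[2L]], ";", fixed = TRUE)[[1]])
  kind <- vapply(fields, `[[`, character(1), 3L)
  n_mem <- lengths(members)

  short <- n_mem < 2L
  if (any(short)) {
    warning(sum(short), " record(s) with <2 members skipped")
  }
  demote <- !short & kind == "complex" & n_mem == 2L
  if (any(demote)) {
    warning(sum(demote), " 2-member complex record(s) reclassified as binary")
    kind[demote] <- "binary"
  }
  bad_kind <- !short & kind == "binary" & n_mem > 2L
  if (any(bad_kind)) kind[bad_kind] <- "complex"

  out <- data.frame(record_id = vapply(fields, `[[`, character(1), 1L),
                    kind = kind,
                    detection_method = vapply(fields, `[[`, character(1), 4L),
                    source = vapply(fields, `[[`, character(1), 5L),
                    stringsAsFactors = FALSE)
  out$members <- members
  out <- out[!short, c("record_id", "members", "kind", "detection_method", "source")]
  rownames(out) <- NULL
  out
}

#' Remove predicted interaction records
#'
#' Drops every record whose detection method contains, as a case-insensitive
#' substring, any of the blacklisted phrases. The default blacklist targets
#' computationally inferred interactions (homology transfer and text mining)
#' so that the network is built from experimentally detected contacts only.
#'
#' @param records Interaction records from [read_interactions()].
#' @param blacklist Character vector of phrases.
#' @return Filtered records, input order preserved.
#' @export
filter_predicted <- function(records,
                             blacklist = c("predicted", "interologs mapping",
                                           "confirmational text mining")) {
  dm <- tolower(records$detection_method)
  hit <- Reduce(`|`, lapply(tolower(blacklist), function(b) grepl(b, dm, fixed = TRUE)))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand complex records into pairwise interactions (matrix model)
#'
#' Under the matrix expansion model a complex of k distinct members yields
#' all k(k-1)/2 unordered pairs, since the physical contacts within the
#' complex are unspecified. Binary records yield their single pair.
#' Self-pairs (duplicate member ids within a record) are discarded. Each
#' output pair carries provenance flags recording whether it is supported by
#' binary and/or expanded-complex evidence; flags are OR-merged across
#' records producing the same pair.
#'
#' @param records Interaction records.
#' @return `data.frame` with columns `a`, `b` (ids, `a < b`), `has_binary`,
#'   `has_complex`.
#' @export
expand_complexes <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      has_binary = logical(0), has_complex = logical(0)))
  }
  per_record <- mapply(function(m, kind) {
    m <- unique(m)
    if (length(m) < 2L) return(NULL)
    cmb <- utils::combn(sort(m), 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ],
               has_binary = kind == "binary",
               has_complex = kind == "complex",
               stringsAsFactors = FALSE)
  }, records$members, records$kind, SIMPLIFY = FALSE)
  pairs <- do.call(rbind, per_record)
  if (is.null(pairs)) {
    return(data.frame(a = character(0), b = character(0),
                      has_binary = logical(0), has_complex = logical(0)))
  }
  key <- paste(pairs$a, pairs$b, sep = "\r")
  agg_bin <- tapply(pairs$has_binary, key, any)
  agg_cpx <- tapply(pairs$has_complex, key, any)
  keys <- names(agg_bin)
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(a = ab[, 1L], b = ab[, 2L],
                    has_binary = as.logical(agg_bin),
                    has_complex = as.logical(agg_cpx),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build an undirected interaction network from expanded pairs
#'
#' Produces a simple undirected graph (no self-loops, no multi-edges);
#' provenance flags are OR-merged across duplicate pairs.
#'
#' @param pairs Pair table from [expand_complexes()], or any `data.frame`
#'   with columns `a`, `b` and optional logical `has_binary`/`has_complex`.
#' @param extra_nodes Character vector of node ids to include even if they
#'   have no edges.
#' @return A `ppi_network`: a list wrapping an `igraph` object (`$graph`)
#'   with logical edge attributes `has_binary` and `has_complex`.
#' @export
build_network <- function(pairs, extra_nodes = character(0)) {
  if (is.null(pairs$has_binary))  pairs$has_binary  <- rep(TRUE, nrow(pairs))
  if (is.null(pairs$has_complex)) pairs$has_complex <- rep(FALSE, nrow(pairs))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  # canonical orientation + dedup with OR-merge
  flip <- pairs$a > pairs$b
  tmp <- pairs$a[flip]; pairs$a[flip] <- pairs$b[flip]; pairs$b[flip] <- tmp
  key <- paste(pairs$a, pairs$b, sep = "\r")
  if (anyDuplicated(key)) {
    agg_bin <- tapply(pairs$has_binary, key, any)
    agg_cpx <- tapply(pairs$has_complex, key, any)
    ab <- do.call(rbind, strsplit(names(agg_bin), "\r", fixed = TRUE))
    pairs <- data.frame(a = ab[, 1L], b = ab[, 2L],
                        has_binary = as.logical(agg_bin),
                        has_complex = as.logical(agg_cpx),
                        stringsAsFactors = FALSE)
  }
  nodes <- unique(c(pairs$a, pairs$b, extra_nodes))
  g <- igraph::graph_from_data_frame(
    pairs[, c("a", "b", "has_binary", "has_complex"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Node ids of a ppi_network
#' @param net A `ppi_network`.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Edge table of a ppi_network
#' @param net A `ppi_network`.
#' @return `data.frame` with columns `a`, `b`, `has_binary`, `has_complex`.
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e)[1:2] <- c("a", "b")
  e
}

#' Basic network statistics
#'
#' Density is the undirected definition 2|E| / (|V| (|V|-1)), the ratio of
#' realized to theoretically possible edges; reported as a fraction.
#'
#' @param net A `ppi_network`.
#' @return List with `degrees` (named integer), `density` (numeric
#'   fraction), `n_nodes`, `n_edges`, and `components` (list of node-id
#'   vectors).
#' @export
network_stats <- function(net) {
  g <- net$graph
  nv <- igraph::vcount(g)
  if (nv < 2L) {
    warning("density undefined for networks with fewer than 2 nodes; reporting 0")
    dens <- 0
  } else {
    dens <- 2 * igraph::ecount(g) / (nv * (nv - 1))
  }
  comp <- igraph::components(g)
  comps <- split(igraph::V(g)$name, comp$membership)
  names(comps) <- NULL
  list(degrees = igraph::degree(g),
       density = dens,
       n_nodes = nv,
       n_edges = igraph::ecount(g),
       components = comps)
}

#' Undirected graph density from printed network sizes
#' @param n_nodes,n_edges Node and edge counts.
#' @return Density as a fraction.
#' @export
graph_density <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Shortest-path network distances to a source set
#'
#' Unweighted breadth-first distances from each network node to a set of
#' source proteins. For every node, reports the minimum distance over the
#' sources, the number of distinct source proteins attaining that minimum,
#' and the source proteins at distance exactly 1 (direct interactors).
#' A node that is itself a source has distance 0. Unreachable nodes and
#' sources absent from the network yield `NA`.
#'
#' @param net A `ppi_network`.
#' @param sources Character vector of source protein ids.
#' @return `data.frame` indexed by node id with columns `id`, `dist`,
#'   `n_at_min`, plus a list column `sources_at_1`.
#' @export
shortest_distances <- function(net, sources) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  src <- intersect(sources, nodes)
  out <- data.frame(id = nodes, dist = NA_real_, n_at_min = NA_integer_,
                    stringsAsFactors = FALSE)
  out$sources_at_1 <- rep(list(character(0)), length(nodes))
  if (length(src) == 0L) {
    if (length(sources)) warning("no source protein present in the network")
    return(out)
  }
  d <- igraph::distances(g, v = src, to = igraph::V(g), algorithm = "unweighted")
  # d: rows = sources, cols = nodes
  mind <- apply(d, 2L, min)
  reach <- is.finite(mind)
  out$dist[reach] <- mind[reach]
  out$n_at_min[reach] <- vapply(which(reach), function(j) {
    sum(d[, j] == mind[j])
  }, integer(1))
  at1 <- lapply(seq_along(nodes), function(j) src[d[, j] == 1])
  out$sources_at_1 <- at1
  out
}

#' Extract the shortest-path subnetwork between two protein sets
#'
#' Returns the subnetwork induced on: the members of both sets present in
#' the parent network, every node lying on at least one geodesic (shortest
#' path) between any pair (a in A, b in B), and any explicitly supplied
#' extra node set (e.g. known interactor lists). A node v lies on a
#' geodesic a-b iff d(a,v) + d(v,b) = d(a,b).
#'
#' @param net Parent `ppi_network`.
#' @param set_a,set_b Character vectors of protein ids.
#' @param keep Extra node ids to retain regardless of geodesic membership.
#' @return A `ppi_network` induced on the selected nodes.
#' @export
extract_subnetwork <- function(net, set_a, set_b, keep = character(0)) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  a_in <- intersect(set_a, nodes)
  b_in <- intersect(set_b, nodes)
  on_path <- character(0)
  if (length(a_in) && length(b_in)) {
    da <- igraph::distances(g, v = a_in, algorithm = "unweighted")
    db <- igraph::distances(g, v = b_in, algorithm = "unweighted")
    sel <- logical(length(nodes))
    for (i in seq_along(a_in)) {
      for (j in seq_along(b_in)) {
        dij <- da[i, b_in[j]]
        if (is.finite(dij)) {
          sel <- sel | (da[i, ] + db[j, ] == dij)
        }
      }
    }
    on_path <- nodes[sel]
  }
  sub_nodes <- unique(c(a_in, b_in, on_path, intersect(keep, nodes)))
  sg <- igraph::induced_subgraph(g, vids = sub_nodes)
  structure(list(graph = sg), class = "ppi_network")
}

#' Network-derived candidate features
#'
#' For each candidate protein computes the bait network distance, the
#' minimum distance to the seed set (with the number of seed proteins
#' attaining it and the seeds at distance 1), the node degree, and the
#' `not_complex` flag (TRUE iff the candidate shares no complex-evidence
#' edge with any *other* candidate, i.e. its candidate contacts are
#' specific rather than co-complex). Candidates absent from the distance
#' network get `NA` for all network fields.
#'
#' @param net `ppi_network` used for distances (shortest-path subnetwork).
#' @param candidates Character vector of candidate ids.
#' @param bait Bait protein id.
#' @param seeds Character vector of seed (disease) protein ids.
#' @param degree_net Optional `ppi_network` in which degree is counted
#'   (defaults to `net`); the full parent interactome in the standard
#'   workflow.
#' @return `data.frame` with one row per candidate: `id`, `parkin_nd`,
#'   `seed_nd`, `seed_nd_count`, `seed_interactors` (comma-joined),
#'   `degree`, `not_complex`.
#' @export
candidate_network_features <- function(net, candidates, bait, seeds,
                                       degree_net = net) {
  nodes <- network_nodes(net)
  bait_d <- shortest_distances(net, bait)
  seed_d <- shortest_distances(net, seeds)
  deg_nodes <- network_nodes(degree_net)
  deg <- igraph::degree(degree_net$graph)

  # complex-evidence adjacency among candidates, in the degree (parent) net
  e <- network_edges(degree_net)
  ec <- e[e$has_complex & e$a %in% candidates & e$b %in% candidates, , drop = FALSE]
  has_cand_complex <- unique(c(ec$a, ec$b))

  rows <- lapply(candidates, function(id) {
    present <- id %in% nodes
    if (!present) {
      return(data.frame(id = id, parkin_nd = NA_real_, seed_nd = NA_real_,
                        seed_nd_count = NA_integer_,
                        seed_interactors = NA_character_,
                        degree = if (id %in% deg_nodes) unname(deg[id]) else NA_integer_,
                        not_complex = NA, stringsAsFactors = FALSE))
    }
    i <- match(id, bait_d$id)
    s <- match(id, seed_d$id)
    ints <- seed_d$sources_at_1[[s]]
    data.frame(id = id,
               parkin_nd = bait_d$dist[i],
               seed_nd = seed_d$dist[s],
               seed_nd_count = seed_d$n_at_min[s],
               seed_interactors = if (length(ints)) paste(sort(ints), collapse = ",") else "",
               degree = if (id %in% deg_nodes) unname(deg[id]) else NA_integer_,
               not_complex = !(id %in% has_cand_complex),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a network as an edge-list TSV
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  e <- network_edges(net)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
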