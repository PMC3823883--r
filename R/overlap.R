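#' Map a gene set through an ortholog table
#'
#' Applies a two-column (source, target) ortholog mapping; the map may be
#' many-to-many, and a source gene mapping to several targets contributes
#' them all. Sources without any mapping are returned separately.
#'
#' @param gene_set Character vector of source ids.
#' @param ortholog_table Two-column `data.frame` (from, to) or TSV path.
#' @return List with `mapped` (character vector of target ids) and
#'   `unmapped` (source ids with no entry).
#' @export
map_orthologs <- function(gene_set, ortholog_table) {
  map <- read_id_map(ortholog_table)
  hits <- map[map$from %in% gene_set, , drop = FALSE]
  list(mapped = unique(hits$to),
       unmapped = setdiff(gene_set, map$from))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the observed overlap |A ∩ B| is larger than expected if A
#' were drawn at random from the universe: upper-tail hypergeometric with
#' sample A, successes B. The universe can be given as a member vector (set
#' members outside it are dropped with a warning) or as a bare size when
#' only the total count is known; results always carry the universe label
#' since the p-value depends strongly on that choice.
#'
#' @param set_a,set_b Character vectors.
#' @param universe Character vector of universe members, or a single number
#'   (universe size; no membership restriction applied).
#' @param label Universe label carried into the result.
#' @return One-row `data.frame`: `n_a`, `n_b`, `overlap`, `universe_size`,
#'   `universe`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe, label = "universe") {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    if (N <= 0L) stop("empty universe")
  } else {
    universe <- unique(universe)
    N <- length(universe)
    if (N == 0L) stop("empty universe")
    out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
    if (length(out_a) || length(out_b)) {
      warning(length(out_a) + length(out_b),
              " set member(s) outside the universe dropped")
    }
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
  }
  k <- length(intersect(set_a, set_b))
  data.frame(n_a = length(set_a), n_b = length(set_b), overlap = k,
             universe_size = N, universe = label,
             p = hypergeom_upper_tail(k, length(set_a), length(set_b), N),
             stringsAsFactors = FALSE)
}

#' Membership flags of candidates against labelled gene sets
#'
#' Produces the external-evidence boolean columns of the feature table:
#' for each labelled set (fly-screen ortholog sets, a previous bait screen,
#' tag-interactor artifact sets, ...), whether each candidate is a member.
#'
#' @param candidates Character vector of candidate ids.
#' @param flag_sets Named list of character vectors.
#' @return `data.frame` with column `id` plus one logical column per label.
#' @export
flag_candidates <- function(candidates, flag_sets) {
  out <- data.frame(id = candidates, stringsAsFactors = FALSE)
  for (nm in names(flag_sets)) {
    out[[nm]] <- candidates %in% flag_sets[[nm]]
  }
  out
}
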