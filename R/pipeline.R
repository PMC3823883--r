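#' Run the full prioritization pipeline
#'
#' Orchestrates every stage on file inputs: loads the protein sets, builds
#' the filtered interactome (predicted records removed, complexes
#' matrix-expanded), extracts the candidate-seed shortest-path subnetwork
#' and computes network features, loads the ontology and annotations,
#' computes slim membership, the seed functional-similarity flags and the
#' shared-GO-term flags, maps the external screens through the ortholog
#' table, assembles the feature table, assigns selection levels and ranks
#' the candidates. Outputs are written as TSVs when `out_dir` is given;
#' reruns on identical inputs are deterministic.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{interactions, ontology, annotations, sets}{input file paths
#'       ([read_interactions()], [load_ontology()], [read_annotations()],
#'       [read_protein_sets()] formats); `sets` must define labels
#'       `candidates`, `seeds` and `bait`, and may define `pink1tap`,
#'       `fly_parkin_screen`, `fly_pink1_screen`.}
#'     \item{orthologs}{optional ortholog table path (fly -> human), needed
#'       when fly screen sets are present.}
#'     \item{comparison_terms}{optional character vector of GO-comparison
#'       term ids; when absent and `reference_set` is given, derived by
#'       dual significance ([shared_term_flags()]).}
#'     \item{slim_terms}{character vector of GO slim term ids.}
#'     \item{funsim_threshold, classic_cutoff}{thresholds (defaults 0.7,
#'       1e-3).}
#'     \item{calmodulin}{optional id whose interactome neighbours are
#'       flagged as tag-binding artifacts.}
#'   }
#' @param out_dir Optional output directory for the stage TSVs.
#' @return List with `hnet`, `spnet`, `network_features`, `features`,
#'   `levels`, `ranked`, `flags`, and the loaded `registry`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  required <- c("interactions", "ontology", "annotations", "sets")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("pipeline config is missing field(s): ", paste(missing, collapse = ", "))
  }
  for (f in c(required, intersect("orthologs", names(config)))) {
    if (!file.exists(config[[f]])) stop("input path for '", f, "' does not exist: ",
                                        config[[f]])
  }
  funsim_threshold <- config$funsim_threshold %||% 0.7
  classic_cutoff <- config$classic_cutoff %||% 1e-3

  registry <- read_protein_sets(config$sets)
  candidates <- get_set(registry, "candidates")
  seeds <- get_set(registry, "seeds")
  bait <- get_set(registry, "bait")[1]

  ## interactome
  records <- filter_predicted(read_interactions(config$interactions))
  pairs <- expand_complexes(records)
  hnet <- build_network(pairs)
  spnet <- extract_subnetwork(hnet, candidates, seeds, keep = bait)
  netf <- candidate_network_features(spnet, candidates, bait, seeds,
                                     degree_net = hnet)

  ## ontology + annotations
  dag <- load_ontology(config$ontology)
  ann <- propagate_annotations(dag, read_annotations(config$annotations))
  ic <- information_content(ann, dag)

  goslim <- if (!is.null(config$slim_terms)) {
    slim_membership(ann, config$slim_terms, dag, proteins = candidates)
  } else stats::setNames(rep(FALSE, length(candidates)), candidates)

  funsim <- funsim_seed_flags(candidates, seeds, ann, dag, ic,
                              threshold = funsim_threshold)

  gocomp <- if (!is.null(config$comparison_terms)) {
    shared_term_flags(NULL, NULL, dag, ann, candidates,
                      comparison_terms = config$comparison_terms)
  } else {
    ref <- if ("reference_set" %in% names(registry$sets)) {
      get_set(registry, "reference_set")
    } else unique(c(seeds, bait))
    res_a <- classic_enrichment(candidates, ann, dag)
    res_b <- classic_enrichment(ref, ann, dag)
    shared_term_flags(res_a, res_b, dag, ann, candidates,
                      cutoff = classic_cutoff)
  }

  ## external evidence flags
  flag_sets <- list()
  if ("pink1tap" %in% names(registry$sets)) {
    flag_sets$pink1tap <- get_set(registry, "pink1tap")
  }
  if (!is.null(config$orthologs)) {
    if ("fly_parkin_screen" %in% names(registry$sets)) {
      flag_sets$parkin_gs <- map_orthologs(get_set(registry, "fly_parkin_screen"),
                                           config$orthologs)$mapped
    }
    if ("fly_pink1_screen" %in% names(registry$sets)) {
      flag_sets$pink1_gs <- map_orthologs(get_set(registry, "fly_pink1_screen"),
                                          config$orthologs)$mapped
    }
  }
  if (!is.null(config$calmodulin) && config$calmodulin %in% network_nodes(hnet)) {
    flag_sets$calmodulin_ip <- igraph::V(hnet$graph)$name[
      igraph::neighbors(hnet$graph, config$calmodulin)]
  }
  external <- flag_candidates(candidates, flag_sets)

  features <- build_features(candidates, netf, gocomp$flags, funsim, goslim,
                             external, symbols = registry$symbols, bait = bait)
  levels <- assign_selection_level(features)
  ranked <- rank_table(features, levels)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(ranked, file.path(out_dir, "ranked_candidates.tsv"))
    write_network(hnet, file.path(out_dir, "hnet_edges.tsv"))
    write_network(spnet, file.path(out_dir, "spnet_edges.tsv"))
    utils::write.table(netf[, setdiff(names(netf), "seed_interactors_list")],
                       file.path(out_dir, "network_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(registry = registry, hnet = hnet, spnet = spnet,
       network_features = netf, features = features, levels = levels,
       ranked = ranked,
       flags = list(goslim = goslim, funsim = funsim, gocomp = gocomp,
                    external = external))
}

#' Run the pipeline end-to-end on a synthetic universe
#'
#' Generates (or reuses) a synthetic universe, writes it to disk, runs
#' [run_pipeline()] on the written files and joins the assigned levels with
#' the planted truth.
#'
#' @param cfg A [synth_config()].
#' @param dir Directory for the universe files (a temporary directory by
#'   default).
#' @return List with the pipeline `result`, the `universe`, and `recovery`
#'   (`data.frame`: `id`, planted `level`, `assigned`, `ok`).
#' @export
run_synthetic_pipeline <- function(cfg = synth_config(),
                                   dir = tempfile("synth_universe_")) {
  u <- synthesize_universe(cfg, dir)
  config <- list(interactions = u$paths$interactions,
                 ontology = u$paths$ontology,
                 annotations = u$paths$annotations,
                 sets = u$paths$sets,
                 orthologs = u$paths$orthologs,
                 comparison_terms = u$comparison_terms,
                 slim_terms = u$slim_terms,
                 funsim_threshold = cfg$funsim_threshold)
  res <- run_pipeline(config)
  recovery <- merge(u$truth, res$levels, by = "id")
  recovery <- data.frame(id = recovery$id, level = recovery$level.x,
                         assigned = recovery$level.y,
                         variant = recovery$variant,
                         ok = recovery$level.x == recovery$level.y,
                         stringsAsFactors = FALSE)
  list(result = res, universe = u, recovery = recovery)
}
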