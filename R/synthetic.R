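#' Configuration for the synthetic toy universe
#'
#' Bundles the knobs of the synthetic-data generator. Defaults produce a
#' small but complete universe: a bait, a seed set of disease proteins, a
#' background interactome mixing binary edges and multi-member complexes
#' (a fixed share of records carrying "predicted"-style detection methods
#' that the filter must remove), a biological-process ontology DAG with
#' annotations, two planted functional families, external fly-screen gene
#' sets with an ortholog table, and candidates wired to land on every
#' selection tier.
#'
#' @param seed Integer RNG seed; the whole universe is reproducible from it.
#' @param n_background Number of background proteins.
#' @param n_bg_terms Number of background ontology terms.
#' @param n_bg_edges Number of background binary interaction records.
#' @param n_complexes Number of background complex records.
#' @param complex_size_range Length-2 integer range of complex sizes.
#' @param frac_predicted Fraction of interaction records carrying a
#'   blacklisted detection method (achieved by adding
#'   `round(frac/(1-frac) * n_real)` decoy records, so the final share is
#'   `frac_predicted` up to rounding).
#' @param n_seeds Number of seed (disease) proteins (>= 4).
#' @param tier_counts Named integer vector, count of planted candidates per
#'   selection level `"0"`..`"8"`.
#' @param funsim_threshold Functional-similarity edge/flag threshold.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_background = 120L, n_bg_terms = 30L,
                         n_bg_edges = 150L, n_complexes = 8L,
                         complex_size_range = c(3L, 6L),
                         frac_predicted = 0.2, n_seeds = 4L,
                         tier_counts = stats::setNames(rep(2L, 9L), as.character(0:8)),
                         funsim_threshold = 0.7) {
  stopifnot(n_seeds >= 4L, n_background > 20L,
            complex_size_range[1] >= 3L,
            complex_size_range[2] <= n_background,
            frac_predicted >= 0, frac_predicted < 1,
            all(tier_counts >= 0L))
  if (is.null(names(tier_counts))) names(tier_counts) <- as.character(0:8)
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 n_bg_terms = as.integer(n_bg_terms),
                 n_bg_edges = as.integer(n_bg_edges),
                 n_complexes = as.integer(n_complexes),
                 complex_size_range = as.integer(complex_size_range),
                 frac_predicted = frac_predicted, n_seeds = as.integer(n_seeds),
                 tier_counts = tier_counts,
                 funsim_threshold = funsim_threshold),
            class = "synth_config")
}

#' Generate the background of the synthetic universe
#'
#' Builds (in memory) the ontology DAG, the background protein annotations,
#' the background interactome records (binary + complexes + predicted
#' decoys), the ortholog table and the pathway collection. Candidates are
#' added on top by [plant_candidates()]. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_universe` list with elements `cfg`, `bait`, `seeds`,
#'   `background`, `obo_lines`, `annotations` (`data.frame`), `records`
#'   (`data.frame` in the [read_interactions()] layout, pre-expansion),
#'   `orthologs`, `pathways`, `slim_terms`, `comparison_terms`,
#'   `functional_families`.
#' @export
generate_universe <- function(cfg) {
  set.seed(cfg$seed)
  bait <- "bait"
  seeds <- paste0("seed", seq_len(cfg$n_seeds))
  bg <- sprintf("bg%03d", seq_len(cfg$n_background))

  ## --- ontology ----------------------------------------------------------
  root <- "T0000"
  slim_parent <- "TSLIM"; slim_children <- c("TSLIM1", "TSLIM2")
  comp_parent <- "TCOMP"; comp_child <- "TCOMP1"
  seed_terms <- stats::setNames(paste0("TSEED", seq_len(cfg$n_seeds)), seeds)
  fam_terms <- c(famA = "TFAMA", famB = "TFAMB")
  bg_root <- "TBG000"
  bg_terms <- sprintf("TBG%03d", seq_len(cfg$n_bg_terms))
  # random tree under bg_root, occasional second parent for DAG structure
  bg_parents <- lapply(seq_along(bg_terms), function(i) {
    pool <- c(bg_root, bg_terms[seq_len(i - 1L)])
    p <- sample(pool, 1L)
    if (i > 3L && stats::runif(1) < 0.15) p <- unique(c(p, sample(pool, 1L)))
    p
  })
  term_def <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(list(root), slim_parent),
    stats::setNames(rep(list(slim_parent), 2L), slim_children),
    stats::setNames(list(root), comp_parent),
    stats::setNames(list(comp_parent), comp_child),
    stats::setNames(rep(list(root), length(seed_terms)), unname(seed_terms)),
    stats::setNames(rep(list(root), 2L), unname(fam_terms)),
    stats::setNames(list(root), bg_root),
    stats::setNames(bg_parents, bg_terms))
  obo_lines <- c("format-version: 1.2", "")
  for (id in names(term_def)) {
    obo_lines <- c(obo_lines, "[Term]", paste0("id: ", id),
                   paste0("name: synthetic term ", id),
                   "namespace: biological_process",
                   paste0("is_a: ", term_def[[id]], " ! parent"), "")
  }
  # decoy obsolete term and a Typedef stanza: parsers must skip both
  obo_lines <- c(obo_lines, "[Term]", "id: TOBS", "name: obsolete decoy",
                 "namespace: biological_process", "is_obsolete: true", "",
                 "[Typedef]", "id: part_of", "name: part of", "")

  ## --- background annotations -------------------------------------------
  ann <- list()
  fam_members <- list(famA = sample(bg, 4L), famB = sample(setdiff(bg, NULL), 4L))
  fam_members$famB <- sample(setdiff(bg, fam_members$famA), 4L)
  for (f in names(fam_members)) {
    for (p in fam_members[[f]]) ann[[p]] <- fam_terms[[f]]
  }
  plain_bg <- setdiff(bg, unlist(fam_members))
  for (p in plain_bg) {
    ann[[p]] <- sample(bg_terms, sample(1:3, 1L))
  }
  for (s in seeds) ann[[s]] <- seed_terms[[s]]
  ann[[bait]] <- c(slim_children[1L], bg_terms[1L])

  ## --- background interactome -------------------------------------------
  real_methods <- c("two hybrid", "affinity chromatography", "coimmunoprecipitation")
  pred_methods <- c("predicted by homology", "Interologs Mapping",
                    "confirmational text mining analysis")
  rec <- list()
  add_rec <- function(members, kind, method) {
    rec[[length(rec) + 1L]] <<- list(members = members, kind = kind, method = method)
  }
  # connected random background: spanning chain + random extra edges
  perm <- sample(bg)
  for (i in seq_len(length(perm) - 1L)) {
    add_rec(perm[i:(i + 1L)], "binary", sample(real_methods, 1L))
  }
  n_extra <- max(0L, cfg$n_bg_edges - (length(bg) - 1L))
  for (i in seq_len(n_extra)) {
    add_rec(sample(bg, 2L), "binary", sample(real_methods, 1L))
  }
  for (i in seq_len(cfg$n_complexes)) {
    k <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]), 1L)
    add_rec(sample(bg, k), "complex", sample(real_methods, 1L))
  }
  # bait-seed backbone: every seed is a direct bait interactor
  for (s in seeds) add_rec(c(bait, s), "binary", "coimmunoprecipitation")

  ## --- orthologs + external gene sets -----------------------------------
  fly_bg <- sprintf("fly%03d", seq_len(30L))
  orth <- data.frame(from = fly_bg, to = sample(bg, 30L, replace = TRUE),
                     stringsAsFactors = FALSE)
  # one many-to-many source
  orth <- rbind(orth, data.frame(from = fly_bg[1L], to = sample(bg, 1L)))

  ## --- pathway collection (plumbing) ------------------------------------
  pathways <- list(pathway_a = sample(bg, 12L), pathway_b = sample(bg, 15L))

  structure(list(cfg = cfg, bait = bait, seeds = seeds, background = bg,
                 obo_lines = obo_lines,
                 annotations = ann,
                 records = rec,
                 real_methods = real_methods, pred_methods = pred_methods,
                 orthologs = orth, pathways = pathways,
                 slim_terms = slim_parent,
                 comparison_terms = comp_parent,
                 seed_terms = seed_terms,
                 slim_children = slim_children, comp_child = comp_child,
                 functional_families = fam_members),
            class = "synth_universe")
}

#' Plant candidates at known selection tiers
#'
#' Adds candidates wired to satisfy exactly one selection-level rule and no
#' higher-priority rule (adversarially minimal): a tier-0 candidate shares a
#' binary edge with the bait; tier 1 interacts with two seeds; tier 2
#' interacts with one seed and shares that seed's rare annotation (forcing
#' best-match-average similarity 1); tier 3 comes in two variants (seed
#' interactor that is a previous-screen hit, and a network-absent candidate
#' that is functionally similar and slim-annotated); tier 4 interacts and
#' hits a fly genetic screen (each variant covers one screen); tier 5
#' interacts and is annotated under the comparison term; tier 6 covers the
#' interact-only and funsim-only variants; tier 7 is slim-annotated only;
#' tier 8 gets background wiring only. Predicted decoy records (including a
#' candidate-bait decoy that must be filtered out) are appended last so the
#' final predicted share matches `cfg$frac_predicted`.
#'
#' @param cfg A [synth_config()].
#' @param universe Output of [generate_universe()].
#' @return The universe extended with `candidates`, `truth` (`data.frame`
#'   with `id`, `level`, `variant`), `pink1tap_set`, `fly_screens`
#'   (named list of fly gene sets), and the predicted decoys appended to
#'   `records`.
#' @export
plant_candidates <- function(cfg, universe) {
  u <- universe
  set.seed(cfg$seed + 1L)
  seeds <- u$seeds; bait <- u$bait
  seed_terms <- u$seed_terms
  truth <- list(); cand_ids <- character(0)
  pink1tap_set <- character(0)
  fly_parkin <- character(0); fly_pink1 <- character(0)
  extra_orth <- list()
  add_rec <- function(members, kind, method = "two hybrid") {
    u$records[[length(u$records) + 1L]] <<- list(members = members, kind = kind,
                                                 method = method)
  }
  note <- function(id, level, variant) {
    truth[[length(truth) + 1L]] <<- data.frame(id = id, level = level,
                                               variant = variant,
                                               stringsAsFactors = FALSE)
    cand_ids <<- c(cand_ids, id)
  }
  bg_far <- u$background[1:10]   # background attachment points
  bg_ann <- function() sample(sprintf("TBG%03d", 1:cfg$n_bg_terms), 1L)

  for (lv in names(cfg$tier_counts)) {
    n <- cfg$tier_counts[[lv]]
    for (j in seq_len(n)) {
      id <- sprintf("cand_%s_%d", lv, j)
      variant <- "base"
      switch(lv,
        "0" = {                       # direct bait interactor
          add_rec(c(id, bait), "binary")
          u$annotations[[id]] <- bg_ann()
        },
        "1" = {                       # two distinct seed interactions
          add_rec(c(id, seeds[1]), "binary")
          add_rec(c(id, seeds[2]), "binary")
          u$annotations[[id]] <- bg_ann()
        },
        "2" = {                       # interact + functionally similar
          add_rec(c(id, seeds[1]), "binary")
          u$annotations[[id]] <- seed_terms[[seeds[1]]]
        },
        "3" = {
          if (j %% 2L == 1L) {        # interact + previous-screen hit
            variant <- "interact_pink1tap"
            add_rec(c(id, seeds[2]), "binary")
            u$annotations[[id]] <- bg_ann()
            pink1tap_set <- c(pink1tap_set, id)
          } else {                    # funsim + slim, absent from network
            variant <- "funsim_goslim"
            u$annotations[[id]] <- c(seed_terms[[seeds[2]]], u$slim_children[2L])
          }
        },
        "4" = {                       # interact + fly genetic screen hit
          add_rec(c(id, seeds[3]), "binary")
          u$annotations[[id]] <- bg_ann()
          fg <- paste0("fly_", id)
          extra_orth[[length(extra_orth) + 1L]] <- data.frame(
            from = fg, to = id, stringsAsFactors = FALSE)
          if (j %% 2L == 1L) { variant <- "parkin_gs"; fly_parkin <- c(fly_parkin, fg) }
          else { variant <- "pink1_gs"; fly_pink1 <- c(fly_pink1, fg) }
        },
        "5" = {                       # interact + shared enriched GO term
          add_rec(c(id, seeds[4]), "binary")
          u$annotations[[id]] <- u$comp_child
        },
        "6" = {
          if (j %% 2L == 1L) {        # interact only
            variant <- "interact_only"
            add_rec(c(id, seeds[1]), "binary")
            u$annotations[[id]] <- bg_ann()
          } else {                    # funsim only
            variant <- "funsim_only"
            u$annotations[[id]] <- seed_terms[[seeds[4]]]
          }
        },
        "7" = {                       # slim-annotated, no seed proximity
          add_rec(c(id, bg_far[j]), "binary")
          u$annotations[[id]] <- u$slim_children[1L]
        },
        "8" = {                       # nothing: background wiring only
          add_rec(c(id, bg_far[j + 2L]), "binary")
          u$annotations[[id]] <- bg_ann()
        })
      note(id, as.integer(lv), variant)
    }
  }
  # one complex among the tier-8 candidates: exercises not_complex = FALSE
  t8 <- cand_ids[grepl("^cand_8_", cand_ids)]
  if (length(t8) >= 2L) add_rec(c(t8[1:2], bg_far[5L]), "complex",
                                "affinity chromatography")

  # predicted decoys, one adversarial (candidate-bait edge that must be
  # filtered out or the tier-7 candidate would jump to level 0)
  n_real <- length(u$records)
  n_pred <- max(0L, round(cfg$frac_predicted / (1 - cfg$frac_predicted) * n_real))
  if (n_pred > 0L) {
    t7 <- cand_ids[grepl("^cand_7_", cand_ids)]
    if (length(t7)) add_rec(c(t7[1L], bait), "binary", u$pred_methods[1L])
    for (i in seq_len(n_pred - as.integer(length(t7) > 0L))) {
      add_rec(sample(u$background, 2L), "binary", sample(u$pred_methods, 1L))
    }
  }

  u$candidates <- cand_ids
  u$truth <- do.call(rbind, truth)
  u$pink1tap_set <- pink1tap_set
  u$fly_screens <- list(parkin_gs = fly_parkin, pink1_gs = fly_pink1)
  u$orthologs <- rbind(u$orthologs, do.call(rbind, extra_orth))
  u
}

#' Write a synthetic universe to its file formats
#'
#' Emits exactly the formats the pipeline consumes: ontology as OBO,
#' annotations as a GAF-like TSV, interactions as the MITAB-like TSV,
#' ortholog table and gene-set TSVs, and the pathway collection as a
#' GMT-like TSV. Repeated calls with the same universe are byte-identical.
#'
#' @param universe Output of [plant_candidates()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_universe <- function(universe, dir) {
  u <- universe
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    sets = file.path(dir, "protein_sets.tsv"))
  writeLines(u$obo_lines, paths$ontology)

  ann_rows <- unlist(lapply(names(u$annotations), function(p) {
    paste(p, u$annotations[[p]], "IEA", sep = "\t")
  }))
  writeLines(ann_rows, paths$annotations)

  rec_rows <- vapply(seq_along(u$records), function(i) {
    r <- u$records[[i]]
    paste(sprintf("r%04d", i), paste(r$members, collapse = ";"), r$kind,
          r$method, "synthdb", sep = "\t")
  }, character(1))
  writeLines(rec_rows, paths$interactions)

  writeLines(paste(u$orthologs$from, u$orthologs$to, sep = "\t"), paths$orthologs)

  gmt <- vapply(names(u$pathways), function(nm) {
    paste(c(nm, "synthetic pathway", u$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, paths$pathways)

  set_lines <- c(
    paste("candidates", u$candidates, sep = "\t"),
    paste("seeds", u$seeds, sep = "\t"),
    paste("bait", u$bait, sep = "\t"),
    paste("pink1tap", u$pink1tap_set, sep = "\t"),
    paste("fly_parkin_screen", u$fly_screens$parkin_gs, sep = "\t"),
    paste("fly_pink1_screen", u$fly_screens$pink1_gs, sep = "\t"))
  writeLines(set_lines, paths$sets)
  paths
}

#' Generate, plant and write a complete synthetic universe
#'
#' Convenience wrapper: [generate_universe()] + [plant_candidates()] +
#' optional [write_universe()].
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory; if `NULL` nothing is written.
#' @return The planted `synth_universe`, with `$paths` set when written.
#' @export
synthesize_universe <- function(cfg = synth_config(), dir = NULL) {
  u <- plant_candidates(cfg, generate_universe(cfg))
  if (!is.null(dir)) u$paths <- write_universe(u, dir)
  u
}
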