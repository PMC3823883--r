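#' Assemble per-candidate feature vectors
#'
#' Joins the outputs of the upstream analyses into one row per candidate:
#' network features (bait distance, seed distance and count, direct seed
#' interactors, degree, not-complex flag), the shared-GO-term flag, the
#' seed functional-similarity flag, the GO-slim flag, and the external
#' evidence flags. Candidates absent from an upstream result get missing
#' (`NA`) network fields and `FALSE` flags, mirroring the "-" convention of
#' the exported table.
#'
#' @param candidates Character vector of candidate ids.
#' @param network_features `data.frame` from [candidate_network_features()].
#' @param gocomp Named logical (or `data.frame` with `id`/`gocomp`).
#' @param funsim_seed Named logical from [funsim_seed_flags()].
#' @param goslim Named logical from [slim_membership()].
#' @param external_flags `data.frame` from [flag_candidates()] with any of
#'   the columns `pink1tap`, `parkin_gs`, `pink1_gs`, `calmodulin_ip`.
#' @param symbols Optional named character vector id -> display symbol.
#' @param bait Optional bait id (assigned `parkin_nd` 0 features by
#'   definition if present among candidates).
#' @return `data.frame` with columns `id`, `symbol`, `parkin_nd`, `seed_nd`,
#'   `seed_nd_count`, `seed_interactors`, `not_complex`, `pink1tap`,
#'   `degree`, `gocomp`, `funsim_seed`, `goslim`, `parkin_gs`, `pink1_gs`,
#'   `calmodulin_ip`.
#' @export
build_features <- function(candidates, network_features = NULL, gocomp = NULL,
                           funsim_seed = NULL, goslim = NULL,
                           external_flags = NULL, symbols = NULL, bait = NULL) {
  pick_flag <- function(x, id, col = NULL) {
    if (is.null(x)) return(FALSE)
    if (is.data.frame(x)) {
      i <- match(id, x$id)
      v <- if (is.na(i)) NA else x[[col]][i]
    } else {
      v <- if (id %in% names(x)) x[[id]] else NA
    }
    isTRUE(v)
  }
  rows <- lapply(candidates, function(id) {
    nf <- if (!is.null(network_features)) {
      i <- match(id, network_features$id)
      if (!is.na(i)) network_features[i, ] else NULL
    } else NULL
    data.frame(
      id = id,
      symbol = if (!is.null(symbols) && !is.na(symbols[id])) unname(symbols[id]) else id,
      parkin_nd = if (!is.null(nf)) nf$parkin_nd else NA_real_,
      seed_nd = if (!is.null(nf)) nf$seed_nd else NA_real_,
      seed_nd_count = if (!is.null(nf)) nf$seed_nd_count else NA_integer_,
      seed_interactors = if (!is.null(nf)) nf$seed_interactors else NA_character_,
      not_complex = if (!is.null(nf)) nf$not_complex else NA,
      pink1tap = pick_flag(external_flags, id, "pink1tap"),
      degree = if (!is.null(nf)) nf$degree else NA_integer_,
      gocomp = pick_flag(gocomp, id, "gocomp"),
      funsim_seed = pick_flag(funsim_seed, id),
      goslim = pick_flag(goslim, id),
      parkin_gs = pick_flag(external_flags, id, "parkin_gs"),
      pink1_gs = pick_flag(external_flags, id, "pink1_gs"),
      calmodulin_ip = pick_flag(external_flags, id, "calmodulin_ip"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bait)) {
    # a candidate that IS the bait interacts with it at distance 0
    out$parkin_nd[out$id == bait] <- 0
  }
  missed <- vapply(seq_len(nrow(out)), function(i) {
    all(is.na(out[i, c("parkin_nd", "seed_nd", "degree")])) &&
      !any(unlist(out[i, c("pink1tap", "gocomp", "funsim_seed", "goslim",
                           "parkin_gs", "pink1_gs", "calmodulin_ip")]))
  }, logical(1))
  if (any(missed)) {
    warning(sum(missed), " candidate(s) present in no upstream result: ",
            paste(utils::head(out$id[missed], 5L), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Assign prioritization selection levels (0 = highest, 8 = lowest)
#'
#' First-match decision tree over the candidate feature vector. Writing
#' `interact` for "direct interactor of a seed protein" (seed distance
#' exactly 1):
#'
#' * **0** — known bait interactor in the interactome (bait distance <= 1),
#'   or the bait itself;
#' * **1** — `interact` with two or more distinct seed proteins at the
#'   minimum distance;
#' * **2** — `interact` and functionally similar to a seed protein;
#' * **3** — `interact` and (previous-bait-screen hit or slim-annotated), or
#'   functionally similar and slim-annotated;
#' * **4** — `interact` and hit in either fly genetic screen;
#' * **5** — `interact` and sharing an enriched GO comparison term;
#' * **6** — `interact` or functionally similar;
#' * **7** — annotated to the disease GO slim;
#' * **8** — default.
#'
#' Missing network fields are treated as "not interacting"; missing flags as
#' `FALSE`. The function is total: exactly one rule fires per candidate.
#'
#' @param features `data.frame` from [build_features()] (or a single row, or
#'   any data.frame with the required columns).
#' @return `data.frame` with columns `id`, `level` (integer 0-8) and
#'   `matched_rule` (label of the rule that fired).
#' @export
assign_selection_level <- function(features) {
  f <- features
  tt <- function(x) !is.na(x) & x           # missing treated as FALSE
  interact <- !is.na(f$seed_nd) & f$seed_nd == 1
  multi_seed <- interact & !is.na(f$seed_nd_count) & f$seed_nd_count >= 2
  bait_ip <- !is.na(f$parkin_nd) & f$parkin_nd <= 1

  level <- rep(8L, nrow(f))
  rule <- rep("default", nrow(f))
  assigned <- rep(FALSE, nrow(f))
  set <- function(cond, lv, lab) {
    sel <- cond & !assigned      # first match wins
    level[sel] <<- lv; rule[sel] <<- lab; assigned[sel] <<- TRUE
  }
  set(bait_ip, 0L, "bait_interactor")
  set(multi_seed, 1L, "multiple_seed_interactions")
  set(interact & tt(f$funsim_seed), 2L, "interact_and_funsim")
  set((interact & (tt(f$pink1tap) | tt(f$goslim))) |
        (tt(f$funsim_seed) & tt(f$goslim)), 3L, "interact_or_funsim_plus_annotation")
  set(interact & (tt(f$parkin_gs) | tt(f$pink1_gs)), 4L, "interact_and_genetic_screen")
  set(interact & tt(f$gocomp), 5L, "interact_and_shared_go")
  set(interact | tt(f$funsim_seed), 6L, "interact_or_funsim")
  set(tt(f$goslim), 7L, "slim_annotated")
  data.frame(id = f$id, level = level, matched_rule = rule,
             stringsAsFactors = FALSE)
}

#' Rank candidates by selection level
#'
#' Orders the feature table the way the published candidate summary is
#' printed: by selection level ascending (0 first); within a level,
#' candidates absent from the interaction network come last, the rest are
#' sorted by degree ascending (low-degree candidates make more specific
#' interactions), then by bait distance ascending, with a final stable
#' lexicographic tie-break on the protein id.
#'
#' @param features `data.frame` from [build_features()].
#' @param levels Optional `data.frame` from [assign_selection_level()];
#'   computed if omitted.
#' @return The feature table with `level` and `rank` columns, ordered.
#' @export
rank_table <- function(features, levels = NULL) {
  if (is.null(levels)) levels <- assign_selection_level(features)
  f <- features
  f$level <- levels$level[match(f$id, levels$id)]
  missing_net <- is.na(f$degree)
  ord <- order(f$level,
               missing_net,
               ifelse(missing_net, Inf, f$degree),
               ifelse(is.na(f$parkin_nd), Inf, f$parkin_nd),
               f$id,
               method = "radix")
  f <- f[ord, , drop = FALSE]
  f$rank <- seq_len(nrow(f))
  rownames(f) <- NULL
  f[, c("rank", setdiff(names(f), "rank"))]
}

#' Read a candidate feature table in the published dialect
#'
#' Parses a TSV with header columns
#' `Rank, Entrez Gene ID, HGNC Symbol, Parkin ND, MonogenicPD ND,
#' MonogenicPD #ND, iMonogenicPD, Not Complex, Pink1TAP, HNet Degree,
#' GOComp, FunSim MonogenicPD, GOSlimPD, ParkinGS, Pink1GS, CalmodulinIP,
#' Selection Level`, where missing/false values are encoded as the en-dash
#' "-"/"–" and true as "true". `iMonogenicPD` is "0" when there is no
#' direct seed interactor, otherwise a comma-separated symbol list.
#'
#' @param path Path to the TSV.
#' @return `data.frame` in the [build_features()] schema plus
#'   `printed_rank` and `printed_level`.
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  dash <- function(x) x %in% c("-", "–", "—", "")
  num <- function(x) ifelse(dash(x), NA_real_, suppressWarnings(as.numeric(x)))
  boolean <- function(x) !dash(x) & tolower(x) == "true"
  ints <- raw[["iMonogenicPD"]]
  data.frame(
    printed_rank = as.integer(raw[["Rank"]]),
    id = raw[["Entrez Gene ID"]],
    symbol = raw[["HGNC Symbol"]],
    parkin_nd = num(raw[["Parkin ND"]]),
    seed_nd = num(raw[["MonogenicPD ND"]]),
    seed_nd_count = as.integer(num(raw[["MonogenicPD #ND"]])),
    seed_interactors = ifelse(ints == "0" | dash(ints), "",
                              gsub(", *", ",", ints)),
    not_complex = boolean(raw[["Not Complex"]]),
    pink1tap = boolean(raw[["Pink1TAP"]]),
    degree = as.integer(num(raw[["HNet Degree"]])),
    gocomp = boolean(raw[["GOComp"]]),
    funsim_seed = boolean(raw[["FunSim MonogenicPD"]]),
    goslim = boolean(raw[["GOSlimPD"]]),
    parkin_gs = boolean(raw[["ParkinGS"]]),
    pink1_gs = boolean(raw[["Pink1GS"]]),
    calmodulin_ip = boolean(raw[["CalmodulinIP"]]),
    printed_level = as.integer(raw[["Selection Level"]]),
    stringsAsFactors = FALSE)
}

#' Write a feature table in the published dialect
#'
#' Inverse of [read_feature_table()]: missing values and `FALSE` flags are
#' encoded as "-", `TRUE` as "true".
#'
#' @param features Ranked feature table (from [rank_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  enc_num <- function(x) ifelse(is.na(x), "-", format(x, trim = TRUE, scientific = FALSE))
  enc_bool <- function(x) ifelse(!is.na(x) & x, "true", "-")
  out <- data.frame(
    `Rank` = features$rank,
    `Entrez Gene ID` = features$id,
    `HGNC Symbol` = features$symbol,
    `Parkin ND` = enc_num(features$parkin_nd),
    `MonogenicPD ND` = enc_num(features$seed_nd),
    `MonogenicPD #ND` = enc_num(features$seed_nd_count),
    `iMonogenicPD` = ifelse(is.na(features$seed_interactors) |
                              features$seed_interactors == "", "0",
                            features$seed_interactors),
    `Not Complex` = enc_bool(features$not_complex),
    `Pink1TAP` = enc_bool(features$pink1tap),
    `HNet Degree` = enc_num(features$degree),
    `GOComp` = enc_bool(features$gocomp),
    `FunSim MonogenicPD` = enc_bool(features$funsim_seed),
    `GOSlimPD` = enc_bool(features$goslim),
    `ParkinGS` = enc_bool(features$parkin_gs),
    `Pink1GS` = enc_bool(features$pink1_gs),
    `CalmodulinIP` = enc_bool(features$calmodulin_ip),
    `Selection Level` = features$level,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged candidate feature table (published 90-row summary)
#'
#' Loads the transcribed 90-row candidate summary table shipped with the
#' package (the printed feature vectors and selection levels for all
#' candidates passing the first seven selection levels, bait row included).
#'
#' @return `data.frame` from [read_feature_table()].
#' @export
candidate_summary_fixture <- function() {
  read_feature_table(system.file("extdata", "candidate_summary.tsv",
                                 package = "gbanet", mustWork = TRUE))
}

#' Packaged disease GO-slim term list
#'
#' The five representative biological-process terms used as the disease GO
#' slim (cell death; regulation of protein ubiquitination; response to
#' stress; mitochondrion organization; autophagy).
#'
#' @return `data.frame` with columns `term_id`, `name`.
#' @export
goslim_pd_terms <- function() {
  utils::read.delim(system.file("extdata", "goslim_pd.tsv", package = "gbanet",
                                mustWork = TRUE),
                    header = TRUE, sep = "\t", colClasses = "character")
}

#' Packaged screen dataset size expectations
#'
#' Published sizes of the screen's named protein datasets and their
#' pairwise overlaps (counts only; membership lists are not part of the
#' published article text).
#'
#' @return `data.frame` with columns `label`, `description`, `size`.
#' @export
dataset_size_expectations <- function() {
  utils::read.delim(system.file("extdata", "dataset_sizes.tsv",
                                package = "gbanet", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
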