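#' Read named protein sets from a tab-delimited file
#'
#' Parses a two- or three-column TSV (`set_label TAB protein_id [TAB symbol]`,
#' no header, `#` comment lines skipped) into a registry of named protein
#' sets. All downstream comparisons between sets are made on the identifier
#' alone; symbols are carried only for display. An optional two-column
#' identifier mapping (old id TAB new id) is applied before set construction;
#' the mapping may be many-to-many, in which case a source id contributes
#' every mapped target. Identifiers absent from the map are retained verbatim
#' and reported via [unmapped_ids()].
#'
#' @param path Path to the tab-delimited set file.
#' @param id_map Optional two-column `data.frame` (from, to) or path to a
#'   TSV in that layout.
#' @return An object of class `set_registry`: a list with elements `sets`
#'   (named list of character id vectors), `symbols` (named character vector
#'   id -> symbol, possibly empty) and `unmapped` (character vector of ids
#'   that had no entry in `id_map`).
#' @export
read_protein_sets <- function(path, id_map = NULL) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    warning("empty set file: ", path)
    return(new_set_registry(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 2L)) {
    stop("set file ", path, ": line ", which(ncol < 2L)[1],
         " has fewer than 2 tab-delimited columns (set_label, protein_id)")
  }
  labels <- vapply(fields, `[[`, character(1), 1L)
  ids    <- vapply(fields, `[[`, character(1), 2L)
  syms   <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_,
                   character(1))
  keep <- nzchar(ids)
  labels <- labels[keep]; ids <- ids[keep]; syms <- syms[keep]

  unmapped <- character(0)
  if (!is.null(id_map)) {
    map <- read_id_map(id_map)
    mapped <- split_map_lookup(ids, map)
    unmapped <- unique(ids[!(ids %in% map$from)])
    labels <- rep(labels, lengths(mapped))
    syms   <- rep(syms, lengths(mapped))
    ids    <- unlist(mapped, use.names = FALSE)
  }

  sets <- lapply(split(ids, factor(labels, levels = unique(labels))), unique)
  symbols <- syms[!is.na(syms)]
  names(symbols) <- ids[!is.na(syms)]
  symbols <- symbols[!duplicated(names(symbols))]
  new_set_registry(sets, symbols = symbols, unmapped = unmapped)
}

new_set_registry <- function(sets, symbols = character(0), unmapped = character(0)) {
  structure(list(sets = sets, symbols = symbols, unmapped = unmapped),
            class = "set_registry")
}

#' @export
print.set_registry <- function(x, ...) {
  cat("set_registry with", length(x$sets), "sets\n")
  for (nm in names(x$sets)) cat("  ", nm, ": ", length(x$sets[[nm]]), " members\n", sep = "")
  invisible(x)
}

# read a two-column from/to mapping table (data.frame or TSV path)
read_id_map <- function(id_map) {
  if (is.character(id_map) && length(id_map) == 1L) {
    lines <- read_tsv_lines(id_map)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, integer(1)) >= 2L
    id_map <- data.frame(from = vapply(fields[ok], `[[`, character(1), 1L),
                         to   = vapply(fields[ok], `[[`, character(1), 2L),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(id_map), ncol(id_map) >= 2L)
  names(id_map)[1:2] <- c("from", "to")
  id_map
}

# map each id through a many-to-many table; unmapped ids pass through
split_map_lookup <- function(ids, map) {
  tab <- split(map$to, map$from)
  lapply(ids, function(i) {
    hit <- tab[[i]]
    if (is.null(hit)) i else unique(hit)
  })
}

#' Ids that failed identifier mapping during set loading
#' @param registry A `set_registry`.
#' @return Character vector of source ids with no mapping entry.
#' @export
unmapped_ids <- function(registry) registry$unmapped

#' Retrieve one named set from a registry
#' @param registry A `set_registry`.
#' @param label Set label.
#' @return Character vector of member ids.
#' @export
get_set <- function(registry, label) {
  if (!label %in% names(registry$sets)) stop("unknown set label: ", label)
  registry$sets[[label]]
}

#' Combine named sets by set algebra
#'
#' @param registry A `set_registry`.
#' @param labels Character vector of set labels (all must exist).
#' @param mode One of `"union"`, `"intersection"`, `"difference"`
#'   (difference is left-fold: first set minus the rest).
#' @param label Label for the derived set; default is constructed from the
#'   inputs.
#' @return The input registry with the derived set appended.
#' @export
combine_sets <- function(registry, labels,
                         mode = c("union", "intersection", "difference"),
                         label = NULL) {
  mode <- match.arg(mode)
  missing <- setdiff(labels, names(registry$sets))
  if (length(missing)) stop("unknown set label(s): ", paste(missing, collapse = ", "))
  members <- registry$sets[labels]
  out <- switch(mode,
    union        = Reduce(union, members),
    intersection = Reduce(intersect, members),
    difference   = Reduce(setdiff, members))
  if (is.null(out)) out <- character(0)
  if (is.null(label)) label <- paste0(mode, "(", paste(labels, collapse = ","), ")")
  registry$sets[[label]] <- unique(out)
  registry
}

#' Pairwise overlap sizes between named sets
#'
#' For each requested pair of sets, reports the intersection size, and the
#' intersection size after removing one designated protein (the bait is
#' conventionally excluded when counting screen overlaps, so that the tagged
#' protein itself does not inflate the comparison).
#'
#' @param registry A `set_registry`.
#' @param pairs List of length-2 character vectors (label, label).
#' @param exclude Optional single protein id removed before the second count.
#' @return `data.frame` with columns `set_a`, `set_b`, `overlap`,
#'   `overlap_excluding`.
#' @export
summarize_overlaps <- function(registry, pairs, exclude = NULL) {
  rows <- lapply(pairs, function(p) {
    a <- get_set(registry, p[[1]]); b <- get_set(registry, p[[2]])
    ab <- intersect(a, b)
    data.frame(set_a = p[[1]], set_b = p[[2]],
               overlap = length(ab),
               overlap_excluding = length(setdiff(ab, exclude)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a registry back to the set-file dialect
#' @param registry A `set_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_sets <- function(registry, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(registry$sets)) {
    for (id in registry$sets[[nm]]) {
      sym <- registry$symbols[id]
      line <- if (!is.na(sym) && length(sym)) paste(nm, id, sym, sep = "\t")
              else paste(nm, id, sep = "\t")
      writeLines(line, con)
    }
  }
  invisible(path)
}

# shared TSV line reader: UTF-8, '#' comments and blank lines skipped
read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
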