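feature_cols <- c("feature_id", "mode", "mz", "rt_apex", "height", "xic")
annotation_cols <- c(
  "feature_id", "rank", "structure_id", "molecular_formula",
  "npc_pathway", "npc_superclass", "npc_class",
  "taxonomic_distance_score", "final_score", "closest_organism",
  "taxon_level"
)

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

# inline XIC serialization: "t:i;t:i;..." with times in minutes
xic_deflate <- function(tr) {
  paste(sprintf("%.10g:%.10g", tr$time, tr$intensity), collapse = ";")
}

xic_inflate <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- vapply(parts, function(p) as.double(p), double(2))
  trace_tbl(m[1, ], m[2, ])
}

#' Read an MS feature table
#'
#' Parses a delimited feature list (one row per feature) with columns
#' `feature_id`, `mz`, `rt_apex`, `height` and `xic` (inline points
#' serialized as `t:i;t:i;...`, times in minutes). Features come back
#' sorted by apex retention time with their XIC traces attached.
#'
#' @param path Path to a delimited text file.
#' @param mode Ionization mode label recorded on the features
#'   (`"pos"`/`"neg"`); taken from the file's `mode` column when present.
#' @param delim Field delimiter (default tab; use `","` for CSV).
#' @return A feature tibble with an `xic` list column of trace tibbles.
#' @export
read_features <- function(path, mode = NULL, delim = "\t") {
  df <- read_delim_quiet(path, delim)
  check_columns(df, c("feature_id", "mz", "rt_apex", "height", "xic"),
                "feature table")
  if (anyDuplicated(df$feature_id)) {
    abort("feature table contains duplicated feature_id values.")
  }
  if (is.null(mode) && !"mode" %in% names(df)) {
    abort("supply `mode` or include a `mode` column.")
  }
  df |>
    mutate(
      feature_id = as.integer(feature_id),
      mode = if ("mode" %in% names(df)) as.character(.data$mode) else mode,
      xic = purrr::map(as.character(xic), xic_inflate)
    ) |>
    arrange(rt_apex) |>
    select(all_of(feature_cols))
}

#' Write an MS feature table
#'
#' @param features Feature tibble (see [read_features()]).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, delim = "\t") {
  features |>
    mutate(xic = purrr::map_chr(xic, xic_deflate)) |>
    readr::write_delim(path, delim = delim)
  invisible(path)
}

#' Read a candidate annotation table
#'
#' Parses the ranked structure hypotheses produced by external annotation
#' engines: per feature and rank, a stereochemistry-free structure key,
#' molecular formula, chemical pathway/superclass/class, the taxonomic
#' distance score (0.9 = structure already reported in the studied
#' species, 0.8 = same genus), the composite final confidence score
#' (values above 1 permitted) and the closest organism in which the
#' structure was reported. Rows with unparseable scores are rejected with
#' their row indices.
#'
#' @param path Path to a delimited text file with the annotation columns.
#' @param delim Field delimiter (default tab).
#' @return An annotation tibble, grouped-ready (sorted by `feature_id`,
#'   `rank`).
#' @export
read_annotations <- function(path, delim = "\t") {
  df <- read_delim_quiet(path, delim)
  check_columns(df, annotation_cols, "annotation table")
  if (nrow(df) == 0L) {
    return(tibble(
      feature_id = integer(), rank = integer(), structure_id = character(),
      molecular_formula = character(), npc_pathway = character(),
      npc_superclass = character(), npc_class = character(),
      taxonomic_distance_score = double(), final_score = double(),
      closest_organism = character(), taxon_level = character()
    ))
  }
  tds <- suppressWarnings(as.double(df$taxonomic_distance_score))
  fs <- suppressWarnings(as.double(df$final_score))
  bad <- which(is.na(tds) | is.na(fs) | tds < 0 | fs < 0)
  if (length(bad) > 0L) {
    abort(sprintf("unparseable or negative score(s) at row(s): %s",
                  paste(head(bad, 10L), collapse = ", ")))
  }
  out <- df |>
    mutate(
      feature_id = as.integer(feature_id),
      rank = as.integer(rank),
      taxonomic_distance_score = tds,
      final_score = fs,
      across(c(structure_id, molecular_formula, npc_pathway,
               npc_superclass, npc_class, closest_organism, taxon_level),
             as.character)
    ) |>
    select(all_of(annotation_cols)) |>
    arrange(feature_id, rank)
  dup <- out |> count(feature_id, rank) |> filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort("annotation table has duplicated (feature_id, rank) pairs.")
  }
  out
}

#' Write a candidate annotation table
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, delim = "\t") {
  readr::write_delim(annotations, path, delim = delim)
  invisible(path)
}

#' Write the per-peak report
#'
#' Flattens the report's candidate list column (multiple retained
#' candidates joined with `" | "` per field) and writes one delimited row
#' per reported CAD peak.
#'
#' @param report Report tibble from [build_report()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(report, path, delim = "\t") {
  flat <- report |>
    mutate(
      structure_id = purrr::map_chr(candidates, ~ paste(.x$structure_id, collapse = " | ")),
      molecular_formula = purrr::map_chr(candidates, ~ paste(.x$molecular_formula, collapse = " | ")),
      npc_pathway = purrr::map_chr(candidates, ~ paste(.x$npc_pathway, collapse = " | ")),
      npc_superclass = purrr::map_chr(candidates, ~ paste(.x$npc_superclass, collapse = " | ")),
      npc_class = purrr::map_chr(candidates, ~ paste(.x$npc_class, collapse = " | ")),
      taxon_level = purrr::map_chr(candidates, ~ paste(.x$taxon_level, collapse = " | ")),
      closest_organism = purrr::map_chr(candidates, ~ paste(.x$closest_organism, collapse = " | ")),
      final_score = purrr::map_chr(candidates, ~ paste(format(.x$final_score, trim = TRUE), collapse = " | "))
    ) |>
    select(-candidates)
  readr::write_delim(flat, path, delim = delim)
  invisible(path)
}

#' Read back a written per-peak report
#'
#' @param path Path written by [write_peak_report()].
#' @param delim Field delimiter (default tab).
#' @return A flat tibble (candidates stay `" | "`-joined).
#' @export
read_peak_report <- function(path, delim = "\t") {
  read_delim_quiet(path, delim)
}
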