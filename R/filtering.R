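#' Filter-cascade configuration
#'
#' Parameters of the taxonomic prioritization and confidence filters. The
#' taxonomic distance score encodes how close the organism in which a
#' candidate structure was previously reported is to the studied species:
#' 0.9 means the structure is already known from the same species, 0.8 from
#' the same genus. The final score is the composite annotation confidence;
#' annotations are considered confident strictly above `min_confidence`.
#'
#' @param species_score Taxonomic distance score meaning "reported in the
#'   same species" (default 0.9).
#' @param genus_score Score meaning "reported in the same genus"
#'   (default 0.8); must be lower than `species_score`.
#' @param min_confidence Strict lower bound on the final score for a
#'   confident annotation (default 0.4).
#' @param score_tolerance Absolute tolerance used when matching taxonomic
#'   scores (default 1e-9); avoids exact float comparison.
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(species_score = 0.9, genus_score = 0.8,
                          min_confidence = 0.4, score_tolerance = 1e-9) {
  if (species_score <= genus_score) {
    abort("`species_score` must exceed `genus_score`.")
  }
  structure(
    list(
      species_score = species_score, genus_score = genus_score,
      min_confidence = min_confidence, score_tolerance = score_tolerance
    ),
    class = "filter_config"
  )
}

# best-ranked candidate per feature; alternates ride along in reports
best_candidates <- function(annotations) {
  annotations |>
    group_by(feature_id) |>
    slice_min(rank, n = 1L, with_ties = FALSE) |>
    ungroup()
}

#' Taxonomic prioritization among one peak's shape-majors
#'
#' Within the set of shape-correlated (major) features under one CAD peak:
#' if any feature's best candidate carries the species-level taxonomic
#' distance score, exactly those features are retained; otherwise, if any
#' carries the genus-level score, exactly those; otherwise all pass through
#' (below genus there is no rationale to prefer one reported source over
#' another, and the confidence filter still acts). Retention when several
#' candidates tie at the winning level is deliberate.
#'
#' @param tax_scores Numeric vector of taxonomic distance scores, one per
#'   feature under the peak (best-ranked candidate each).
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where the feature is retained.
#' @export
taxonomic_prioritization <- function(tax_scores, config = filter_config()) {
  tol <- config$score_tolerance
  at <- function(level) !is.na(tax_scores) & abs(tax_scores - level) <= tol
  if (any(at(config$species_score))) {
    at(config$species_score)
  } else if (any(at(config$genus_score))) {
    at(config$genus_score)
  } else {
    rep(TRUE, length(tax_scores))
  }
}

#' Confidence filter
#'
#' Retains candidates whose final score is strictly above the confidence
#' threshold. Scores above 1 are permitted (composite scores can exceed 1
#' when every evidence component saturates) but are flagged for inspection.
#'
#' @param final_scores Numeric vector of final annotation scores.
#' @param config A [filter_config()].
#' @return A tibble with logical columns `retained` and `over_unity`.
#' @export
confidence_filter <- function(final_scores, config = filter_config()) {
  keep <- !is.na(final_scores) & final_scores > config$min_confidence
  tibble(retained = keep, over_unity = keep & final_scores > 1)
}

#' Apply the major/minor filter cascade
#'
#' Runs the three filters in order — peak shape, taxonomic prioritization,
#' annotation confidence — over the links produced by [link_features()] and
#' the candidate annotation table. A feature demoted at any stage is kept
#' in the output as part of the minor metabolome; nothing is ever dropped.
#' Features without any annotation cannot be confidently attributed and are
#' demoted at the confidence stage.
#'
#' @param links Link tibble from [link_features()].
#' @param annotations Candidate annotation tibble (see
#'   [read_annotations()]); every `feature_id` it mentions must exist in
#'   `links`.
#' @param config A [filter_config()].
#' @return An object of class `cad_cascade`: a list with `links` (the input
#'   plus `status_final` and `over_unity`), `retained` (feature ids passing
#'   the full cascade), `stage_counts` (per-stage feature and per-peak
#'   structure counts) and `config`. Use [tidy.cad_cascade()] for the link
#'   table and [glance.cad_cascade()] for the one-row summary.
#' @export
apply_filter_cascade <- function(links, annotations,
                                 config = filter_config()) {
  unknown <- setdiff(unique(annotations$feature_id), links$feature_id)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "annotations reference unknown feature ids: %s",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  best <- best_candidates(annotations)

  work <- links |>
    left_join(
      select(best, feature_id, structure_id,
             taxonomic_distance_score, final_score),
      by = "feature_id"
    )

  # stage 1: peak shape
  shape_major <- work$status_shape == "major"

  # stage 2: taxonomic prioritization per peak among shape-majors
  tax_major <- shape_major
  for (pid in unique(work$peak_id[shape_major & !is.na(work$peak_id)])) {
    idx <- which(shape_major & !is.na(work$peak_id) & work$peak_id == pid)
    keep <- taxonomic_prioritization(
      work$taxonomic_distance_score[idx], config
    )
    tax_major[idx] <- keep
  }

  # stage 3: annotation confidence
  conf <- confidence_filter(work$final_score, config)
  final_major <- tax_major & conf$retained

  out_links <- links |>
    mutate(
      status_final = if_else(final_major, "major", "minor"),
      over_unity = final_major & conf$over_unity
    )

  stage_counts <- bind_rows(
    stage_count_row("none", work, !is.na(work$peak_id)),
    stage_count_row("shape", work, shape_major),
    stage_count_row("shape+taxon", work, tax_major),
    stage_count_row("shape+taxon+confidence", work, final_major)
  )

  structure(
    list(
      links = out_links,
      retained = links$feature_id[final_major],
      stage_counts = stage_counts,
      config = config
    ),
    class = "cad_cascade"
  )
}

# per-stage summary: surviving linked features and, per peak, the number of
# distinct candidate structures among survivors
stage_count_row <- function(stage, work, surviving) {
  linked <- surviving & !is.na(work$peak_id)
  per_peak <- work |>
    filter(linked) |>
    group_by(peak_id) |>
    summarise(
      n_structures = n_distinct(structure_id[!is.na(structure_id)]),
      .groups = "drop"
    )
  tibble(
    stage = stage,
    features_linked = sum(linked),
    per_peak = list(per_peak)
  )
}

#' @export
tidy.cad_cascade <- function(x, ...) x$links

#' @export
glance.cad_cascade <- function(x, ...) {
  sc <- x$stage_counts
  tibble(
    n_features = nrow(x$links),
    n_linked = sc$features_linked[sc$stage == "none"],
    n_shape_major = sc$features_linked[sc$stage == "shape"],
    n_taxon_major = sc$features_linked[sc$stage == "shape+taxon"],
    n_final_major = sc$features_linked[sc$stage == "shape+taxon+confidence"]
  )
}

#' Turn a model object into a tidy tibble
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
print.cad_cascade <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0(
      "<cad_cascade>\n  features: %d (linked to a CAD peak: %d)\n",
      "  major after shape filter:      %d\n",
      "  major after taxonomic filter:  %d\n",
      "  major after confidence filter: %d\n"
    ),
    g$n_features, g$n_linked, g$n_shape_major, g$n_taxon_major,
    g$n_final_major
  ))
  invisible(x)
}
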