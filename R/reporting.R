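round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summary statistics of the feature-to-peak attribution
#'
#' Computes the tabular run-summary statistics at one filter stage: the number
#' of features linked to a CAD peak that survive the stage and, averaged
#' over the peaks that keep at least one surviving linked feature, the
#' number of features, distinct candidate structures, distinct molecular
#' formulas and distinct chemical classes per peak. Peaks that lose every
#' linked feature are excluded from the averages. Means are rounded
#' half-up to one decimal (the convention of printed run reports).
#'
#' @param links Link tibble; needs `feature_id`, `peak_id` and the status
#'   column for the requested stage (`status_shape` and, after the cascade,
#'   `status_final`).
#' @param annotations Candidate annotation tibble (may have zero rows).
#' @param peaks Peak tibble (used for the picked-peak count).
#' @param stage One of `"none"` (all enveloped features), `"shape"`
#'   (shape-majors) or `"final"` (cascade survivors).
#' @return A one-row tibble: `stage`, `picked_features`, `picked_peaks`,
#'   `features_linked`, `mean_features_per_peak`,
#'   `mean_structures_per_peak`, `mean_mfs_per_peak`,
#'   `mean_classes_per_peak`. Means are `NA` when no feature survives.
#' @export
summarize_links <- function(links, annotations, peaks,
                            stage = c("none", "shape", "final")) {
  stage <- match.arg(stage)
  surviving <- switch(stage,
    none = !is.na(links$peak_id),
    shape = !is.na(links$peak_id) & links$status_shape == "major",
    final = !is.na(links$peak_id) & links$status_final == "major"
  )
  kept <- links[surviving, ]
  best <- if (nrow(annotations) > 0L) best_candidates(annotations) else
    tibble(feature_id = integer(), structure_id = character(),
           molecular_formula = character(), npc_class = character())
  kept <- left_join(
    kept,
    select(best, feature_id, structure_id, molecular_formula, npc_class),
    by = "feature_id"
  )
  per_peak <- kept |>
    group_by(peak_id) |>
    summarise(
      n_features = n(),
      n_structures = n_distinct(structure_id[!is.na(structure_id)]),
      n_mfs = n_distinct(molecular_formula[!is.na(molecular_formula)]),
      n_classes = n_distinct(npc_class[!is.na(npc_class)]),
      .groups = "drop"
    )
  mean1 <- function(x) {
    if (nrow(per_peak) == 0L) NA_real_ else round_half_up(mean(x), 1)
  }
  tibble(
    stage = stage,
    picked_features = nrow(links),
    picked_peaks = nrow(peaks),
    features_linked = nrow(kept),
    mean_features_per_peak = mean1(per_peak$n_features),
    mean_structures_per_peak = mean1(per_peak$n_structures),
    mean_mfs_per_peak = mean1(per_peak$n_mfs),
    mean_classes_per_peak = mean1(per_peak$n_classes)
  )
}

#' Per-peak report of the major metabolome
#'
#' One row per integrated CAD peak that kept at least one linked feature:
#' peaks with confident retained candidates list them (structure, formula,
#' chemical pathway/superclass/class, taxonomic level, closest organism,
#' final score); peaks whose candidates were all demoted appear with an
#' empty candidate list — they are the ones to prioritize for manual
#' structural investigation. Area fractions are relative to the total area
#' of all integrated peaks, so they sum to at most 1 over the report.
#'
#' @param peaks Peak tibble from [detect_peaks()].
#' @param cascade A `cad_cascade` from [apply_filter_cascade()].
#' @param annotations Candidate annotation tibble.
#' @return A report tibble with a `candidates` list column and a `flags`
#'   column (`"over_unity_score"`, `"no_confident_annotation"` or `""`).
#' @export
build_report <- function(peaks, cascade, annotations) {
  links <- cascade$links
  total_area <- sum(peaks$area)
  best <- if (nrow(annotations) > 0L) best_candidates(annotations) else NULL

  linked_peaks <- links |>
    filter(!is.na(peak_id)) |>
    distinct(peak_id) |>
    pull(peak_id)

  rows <- purrr::map(sort(linked_peaks), function(pid) {
    pk <- peaks[peaks$peak_id == pid, ]
    winners <- links |>
      filter(peak_id == pid, status_final == "major")
    cands <- if (!is.null(best) && nrow(winners) > 0L) {
      annotations |>
        filter(feature_id %in% winners$feature_id) |>
        inner_join(select(best, feature_id, rank), by = c("feature_id", "rank")) |>
        select(structure_id, molecular_formula, npc_pathway, npc_superclass,
               npc_class, taxon_level, closest_organism, final_score) |>
        distinct()
    } else {
      tibble(
        structure_id = character(), molecular_formula = character(),
        npc_pathway = character(), npc_superclass = character(),
        npc_class = character(), taxon_level = character(),
        closest_organism = character(), final_score = double()
      )
    }
    flag <- if (nrow(cands) == 0L) {
      "no_confident_annotation"
    } else if (any(winners$over_unity)) {
      "over_unity_score"
    } else {
      ""
    }
    tibble(
      peak_id = pid,
      apex_rt = pk$apex_time,
      area = pk$area,
      area_fraction = if (total_area > 0) pk$area / total_area else 0,
      candidates = list(cands),
      flags = flag
    )
  })
  if (length(rows) == 0L) {
    return(tibble(
      peak_id = integer(), apex_rt = double(), area = double(),
      area_fraction = double(), candidates = list(), flags = character()
    ))
  }
  purrr::list_rbind(rows)
}

#' Pseudochromatogram bar series
#'
#' One bar per reported peak, at its apex retention time, with the
#' integrated (never re-integrated) CAD area as value and a category taken
#' from the retained annotation: the taxonomic level of the closest
#' organism, or the chemical pathway/superclass. Peaks without a confident
#' retained candidate get category `"none"`.
#'
#' @param report Report tibble from [build_report()].
#' @param scheme `"taxon-level"`, `"npc-pathway"` or `"npc-superclass"`.
#' @return A tibble `rt`, `value`, `category`.
#' @export
pseudochromatogram <- function(report,
                               scheme = c("taxon-level", "npc-pathway",
                                          "npc-superclass")) {
  scheme <- match.arg(scheme)
  col <- switch(scheme,
    "taxon-level" = "taxon_level",
    "npc-pathway" = "npc_pathway",
    "npc-superclass" = "npc_superclass"
  )
  if (nrow(report) == 0L) {
    return(tibble(rt = double(), value = double(), category = character()))
  }
  purrr::pmap(report, function(peak_id, apex_rt, area, area_fraction,
                               candidates, flags) {
    category <- if (nrow(candidates) == 0L) "none" else candidates[[col]][1]
    tibble(rt = apex_rt, value = area, category = category)
  }) |>
    purrr::list_rbind()
}

#' Treemap fractions by chemical category
#'
#' With `weight = "cad_area"`, the fraction of the total retained CAD area
#' attributed to each chemical pathway across the final major metabolome
#' (the semiquantitative composition view). With `weight = "count"`, the
#' fraction of annotation counts per pathway across the minor metabolome
#' (MS intensity deliberately neglected — counts, not signal). Fractions
#' sum to 1 for nonempty input.
#'
#' @param report Report tibble from [build_report()].
#' @param cascade A `cad_cascade`.
#' @param annotations Candidate annotation tibble.
#' @param weight `"cad_area"` (majors) or `"count"` (minors).
#' @param category `"npc_pathway"` (default), `"npc_superclass"` or
#'   `"npc_class"`.
#' @return A tibble `category`, `fraction`.
#' @export
treemap_fractions <- function(report, cascade, annotations,
                              weight = c("cad_area", "count"),
                              category = "npc_pathway") {
  weight <- match.arg(weight)
  if (!category %in% c("npc_pathway", "npc_superclass", "npc_class")) {
    abort("unknown treemap category scheme.")
  }
  if (weight == "cad_area") {
    rows <- purrr::pmap(report, function(peak_id, apex_rt, area,
                                         area_fraction, candidates, flags) {
      if (nrow(candidates) == 0L) return(NULL)
      tibble(category = candidates[[category]][1], w = area)
    }) |>
      purrr::list_rbind()
  } else {
    minors <- cascade$links$feature_id[cascade$links$status_final == "minor"]
    best <- if (nrow(annotations) > 0L) best_candidates(annotations) else NULL
    rows <- if (is.null(best)) NULL else best |>
      filter(feature_id %in% minors, !is.na(.data[[category]])) |>
      transmute(category = .data[[category]], w = 1)
  }
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble(category = character(), fraction = double()))
  }
  rows |>
    group_by(category) |>
    summarise(w = sum(w), .groups = "drop") |>
    mutate(fraction = w / sum(w)) |>
    select(category, fraction) |>
    arrange(desc(fraction))
}

#' Alluvial bin table of the filtering process
#'
#' Bins CAD peaks by the number of distinct candidate structures their
#' surviving linked features carry at each cascade stage (bins 0, 1, 2,
#' 3-5, >5). The bins partition the peaks, so per-stage totals are equal.
#'
#' @param cascade A `cad_cascade`.
#' @param peaks Peak tibble (all integrated peaks; peaks with no surviving
#'   feature at a stage fall into the `0` bin).
#' @return A tibble `stage`, `bin`, `n_peaks`.
#' @export
alluvial_counts <- function(cascade, peaks) {
  bins <- c("0", "1", "2", "3-5", ">5")
  bin_of <- function(n) {
    ifelse(n == 0, "0",
      ifelse(n == 1, "1",
        ifelse(n == 2, "2", ifelse(n <= 5, "3-5", ">5"))
      )
    )
  }
  purrr::pmap(cascade$stage_counts, function(stage, features_linked,
                                             per_peak) {
    n_str <- setNames(rep(0L, nrow(peaks)), peaks$peak_id)
    if (nrow(per_peak) > 0L) {
      n_str[as.character(per_peak$peak_id)] <- per_peak$n_structures
    }
    tibble(stage = stage, bin = factor(bin_of(n_str), levels = bins)) |>
      count(stage, bin, name = "n_peaks", .drop = FALSE)
  }) |>
    purrr::list_rbind() |>
    mutate(bin = as.character(bin))
}

#' Decorate a molecular network with CAD information
#'
#' Adds to every node (keyed by feature id) the integrated area of its
#' linked CAD peak (`cad_area`, 0 for minor or unlinked features), its
#' final major/minor status and the chemical pathway of its retained
#' candidate (`"unannotated"` when none). Edges are untouched. Node sizes
#' proportional to `cad_area` give molecular networks a semiquantitative
#' dimension.
#'
#' @param network An `igraph` whose vertex `name` attributes are feature
#'   ids (see [read_network()]).
#' @param peaks Peak tibble.
#' @param cascade A `cad_cascade`.
#' @param annotations Candidate annotation tibble.
#' @return The decorated `igraph`.
#' @export
decorate_network <- function(network, peaks, cascade, annotations) {
  links <- cascade$links
  ids <- suppressWarnings(as.integer(igraph::V(network)$name))
  best <- if (nrow(annotations) > 0L) best_candidates(annotations) else NULL
  areas <- setNames(peaks$area, peaks$peak_id)

  attrs <- purrr::map(ids, function(fid) {
    row <- links[!is.na(fid) & links$feature_id == fid, ]
    if (nrow(row) == 0L) {
      warn(sprintf("network node %s has no link record; using defaults.", fid))
      return(list(cad_area = 0, status_final = "minor",
                  npc_pathway = "unannotated"))
    }
    major <- row$status_final[1] == "major"
    area <- if (major && !is.na(row$peak_id[1])) {
      unname(areas[as.character(row$peak_id[1])])
    } else {
      0
    }
    pw <- "unannotated"
    if (major && !is.null(best)) {
      b <- best[best$feature_id == fid, ]
      if (nrow(b) == 1L && !is.na(b$npc_pathway)) pw <- b$npc_pathway
    }
    list(cad_area = area, status_final = row$status_final[1],
         npc_pathway = pw)
  })
  network <- igraph::set_vertex_attr(
    network, "cad_area", value = purrr::map_dbl(attrs, "cad_area")
  )
  network <- igraph::set_vertex_attr(
    network, "status_final", value = purrr::map_chr(attrs, "status_final")
  )
  igraph::set_vertex_attr(
    network, "npc_pathway", value = purrr::map_chr(attrs, "npc_pathway")
  )
}
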