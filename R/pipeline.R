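#' Run the full attribution workflow on one dataset
#'
#' Chains every stage on in-memory inputs: pretreat all detector traces
#' (lag alignment, FFT denoising, derivative sharpening), detect and
#' integrate CAD peaks on the pretreated native-resolution trace, link MS
#' features to CAD peaks by normalized peak-shape correlation, run the
#' taxonomic/confidence filter cascade, and assemble the report, summary
#' statistics and visualization tables.
#'
#' The detection SNR gate uses the noise level of the raw (pre-denoising)
#' CAD trace so that residual baseline undulation left by the low-pass
#' filter cannot masquerade as peaks. Peak detection runs on the sharpened
#' signal (that is what sharpening is for — resolving apexes and bounds),
#' while peak-shape similarity is computed on the denoised but unsharpened
#' CAD trace: the feature XICs are not sharpened, so comparing them against
#' a derivative-enhanced CAD shape would penalize exactly the matching
#' features.
#'
#' @param chromatograms Chromatogram set tibble (must include a CAD trace).
#' @param features Feature tibble with XICs on the MS time axis.
#' @param annotations Candidate annotation tibble.
#' @param network Optional `igraph` molecular network to decorate.
#' @param pre [pretreat_config()].
#' @param link [link_config()].
#' @param filt [filter_config()].
#' @param min_snr,min_width Peak detection gates (see [detect_peaks()]).
#' @return A list: `cad` (pretreated CAD trace), `peaks`, `links` (with
#'   `status_final`), `cascade`, `report`, `stats` (per-stage
#'   [summarize_links()] rows), `alluvial`, `treemap_major`,
#'   `treemap_minor`, `pseudo`, and `network` (decorated, or `NULL`).
#' @export
run_pipeline <- function(chromatograms, features, annotations,
                         network = NULL,
                         pre = pretreat_config(),
                         link = link_config(),
                         filt = filter_config(),
                         min_snr = 5, min_width = 0.05) {
  cad_raw <- get_trace(chromatograms, "CAD")
  noise_raw <- estimate_noise(align_trace(cad_raw, pre$lag_cad_to_ms))$level
  cad <- pretreat_trace(cad_raw, pre$lag_cad_to_ms, pre, resample = FALSE)
  cad_smooth <- denoise_fft(
    resample_native(align_trace(cad_raw, pre$lag_cad_to_ms)),
    pre$fourier_component_fraction
  )
  peaks <- detect_peaks(cad, min_snr = min_snr, min_width = min_width,
                        noise_level = noise_raw)
  links <- link_features(features, peaks, cad_smooth, link)
  cascade <- apply_filter_cascade(links, annotations, filt)
  report <- build_report(peaks, cascade, annotations)
  stats <- bind_rows(
    summarize_links(cascade$links, annotations, peaks, "none"),
    summarize_links(cascade$links, annotations, peaks, "shape"),
    summarize_links(cascade$links, annotations, peaks, "final")
  )
  list(
    cad = cad,
    peaks = peaks,
    links = cascade$links,
    cascade = cascade,
    report = report,
    stats = stats,
    alluvial = alluvial_counts(cascade, peaks),
    treemap_major = treemap_fractions(report, cascade, annotations, "cad_area"),
    treemap_minor = treemap_fractions(report, cascade, annotations, "count"),
    pseudo = pseudochromatogram(report, "taxon-level"),
    network = if (!is.null(network)) {
      decorate_network(network, peaks, cascade, annotations)
    } else {
      NULL
    }
  )
}

#' Run the workflow and write its artifacts
#'
#' File-level wrapper around [run_pipeline()]: writes the peak list, link
#' table, report, stage statistics, alluvial/treemap/pseudochromatogram
#' tables (TSV/JSON) and the decorated GraphML. Output is deterministic for
#' deterministic input: running twice on the same files yields byte-equal
#' artifacts.
#'
#' @param input_dir Directory holding `chromatograms.mzML`, `features.tsv`,
#'   `annotations.tsv` and optionally `network.graphml` (the layout of
#'   [write_fixture_bundle()]).
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [run_pipeline()].
#' @return Named vector of written paths, invisibly.
#' @export
run_pipeline_files <- function(input_dir, out_dir, ...) {
  chromatograms <- read_chromatograms(file.path(input_dir, "chromatograms.mzML"))
  features <- read_features(file.path(input_dir, "features.tsv"))
  annotations <- read_annotations(file.path(input_dir, "annotations.tsv"))
  net_path <- file.path(input_dir, "network.graphml")
  network <- if (file.exists(net_path)) read_network(net_path) else NULL
  res <- run_pipeline(chromatograms, features, annotations, network, ...)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peaks = file.path(out_dir, "peaks.tsv"),
    links = file.path(out_dir, "links.tsv"),
    report = file.path(out_dir, "report.tsv"),
    stats = file.path(out_dir, "stats.tsv"),
    alluvial = file.path(out_dir, "alluvial.tsv"),
    plots = file.path(out_dir, "plot_data.json")
  )
  readr::write_tsv(res$peaks, paths["peaks"])
  readr::write_tsv(res$links, paths["links"])
  write_peak_report(res$report, paths["report"])
  readr::write_tsv(res$stats, paths["stats"])
  readr::write_tsv(res$alluvial, paths["alluvial"])
  jsonlite::write_json(
    list(
      pseudochromatogram = res$pseudo,
      treemap_major = res$treemap_major,
      treemap_minor = res$treemap_minor
    ),
    paths["plots"],
    digits = NA, auto_unbox = TRUE
  )
  if (!is.null(res$network)) {
    net_out <- file.path(out_dir, "network_decorated.graphml")
    write_network(res$network, net_out)
    paths <- c(paths, network = net_out)
  }
  invisible(paths)
}
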