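#' Specification of a synthetic multi-detector dataset
#'
#' Describes a seeded, ground-truthed acquisition: planted CAD peaks
#' (Gaussian or exponentially modified Gaussian), shape-correlated major
#' feature XICs, shifted decoy XICs, baseline drift and detector noise, and
#' annotation tables with controlled taxonomic/confidence score
#' distributions. The same seed always yields bit-identical output.
#'
#' The defaults emulate a routine natural-extract profiling run: twenty
#' well-separated peaks over a 20 min window, peak widths (sigma) of
#' 0.03-0.08 min, apex heights 50-500 CAD units against 0.5 units of
#' detector noise and a gentle 1-unit baseline wave, CAD sampled at 60 Hz
#' (about 30x the 2 Hz MS1 rate), two shape-correlated features plus three
#' decoys per peak, 2 % multiplicative XIC noise and decoy apex shifts of
#' at least two peak FWHMs.
#'
#' @param n_peaks Number of planted CAD peaks.
#' @param rt_span Retention-time window in minutes, length-2 vector.
#' @param peak_shape `"gaussian"` or `"emg"` (tailing peaks).
#' @param sigma_range Range of peak sigma in minutes.
#' @param apex_height_range Range of apex heights, CAD units.
#' @param n_majors_per_peak,n_decoys_per_peak Count (or range) of planted
#'   shape-correlated and decoy features per peak.
#' @param major_noise_sd_frac Additive XIC noise sd as a fraction of the
#'   XIC apex for major features.
#' @param decoy_shift_min_fwhm Minimum decoy apex shift, in multiples of
#'   the parent peak's FWHM.
#' @param baseline_drift Amplitude of the slow baseline wave, CAD units.
#' @param noise_sd CAD detector noise sd, CAD units.
#' @param frac_species_peaks Fraction of peaks whose major features carry a
#'   species-level, confident best candidate.
#' @param cad_rate,ms_rate Sampling rates, Hz.
#' @param mode Ionization mode label stamped on the features.
#' @param seed Integer seed fixing all randomness.
#' @return A list with class `fixture_spec`.
#' @export
fixture_spec <- function(n_peaks = 20,
                         rt_span = c(0, 20),
                         peak_shape = c("gaussian", "emg"),
                         sigma_range = c(0.03, 0.08),
                         apex_height_range = c(50, 500),
                         n_majors_per_peak = 2,
                         n_decoys_per_peak = 3,
                         major_noise_sd_frac = 0.02,
                         decoy_shift_min_fwhm = 2,
                         baseline_drift = 1,
                         noise_sd = 0.5,
                         frac_species_peaks = 1,
                         cad_rate = 60,
                         ms_rate = 2,
                         mode = "pos",
                         seed = 1) {
  peak_shape <- match.arg(peak_shape)
  span <- diff(rt_span)
  if (n_peaks > 0) {
    margin <- 0.75
    spacing <- if (n_peaks > 1) (span - 2 * margin) / (n_peaks - 1) else span
    if (spacing < 4 * max(sigma_range)) {
      abort("rt_span too short for n_peaks at >= 4 sigma spacing.")
    }
  }
  structure(
    list(
      n_peaks = n_peaks, rt_span = rt_span, peak_shape = peak_shape,
      sigma_range = sigma_range, apex_height_range = apex_height_range,
      n_majors_per_peak = n_majors_per_peak,
      n_decoys_per_peak = n_decoys_per_peak,
      major_noise_sd_frac = major_noise_sd_frac,
      decoy_shift_min_fwhm = decoy_shift_min_fwhm,
      baseline_drift = baseline_drift, noise_sd = noise_sd,
      frac_species_peaks = frac_species_peaks,
      cad_rate = cad_rate, ms_rate = ms_rate, mode = mode,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# unit-apex peak shape centred at mu
peak_shape_fun <- function(shape, mu, sigma) {
  if (shape == "gaussian") {
    function(t) exp(-0.5 * ((t - mu) / sigma)^2)
  } else {
    tau <- 0.6 * sigma
    erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
    f <- function(t) {
      exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
        erfc((sigma / tau - (t - mu) / sigma) / sqrt(2))
    }
    # normalize to unit apex on a dense local grid
    tt <- seq(mu - 4 * sigma, mu + 8 * sigma, length.out = 2001)
    apex <- max(f(tt))
    function(t) f(t) / apex
  }
}

rng_range <- function(n, r) {
  if (length(r) == 1L) rep(r, n) else runif(n, r[1], r[2])
}

count_range <- function(n, r) {
  if (length(r) == 1L) rep(as.integer(r), n)
  else sample(seq(r[1], r[2]), n, replace = TRUE)
}

#' Generate a synthetic multi-detector dataset with ground truth
#'
#' Renders the CAD trace (sum of planted shapes + drift + noise, on the CAD
#' time axis, i.e. shifted 0.055 min earlier than the MS axis), matching
#' PDA and BPI traces, major and decoy feature XICs at the MS rate,
#' a candidate annotation table drawn from the spec's score distributions,
#' a toy molecular network connecting co-eluting features, and the ground
#' truth needed to score recovery.
#'
#' @param spec A [fixture_spec()].
#' @return A list (`chromatograms`, `features`, `annotations`, `network`,
#'   `truth`) where `truth` holds `peaks` (planted apex/sigma/height/area
#'   on the MS axis) and `features` (`feature_id`, `parent_peak`,
#'   `is_major`).
#' @export
simulate_extract <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lag_cad <- 0.055
  lag_pda <- 0.090
  rt0 <- spec$rt_span[1]
  rt1 <- spec$rt_span[2]
  span <- rt1 - rt0

  n <- spec$n_peaks
  if (n > 0) {
    margin <- 0.75
    centers <- if (n > 1) seq(rt0 + margin, rt1 - margin, length.out = n) else
      (rt0 + rt1) / 2
    spacing <- if (n > 1) diff(centers)[1] else span
    apex <- centers + runif(n, -0.05, 0.05) * spacing
    sigma <- rng_range(n, spec$sigma_range)
    height <- rng_range(n, spec$apex_height_range)
    shapes <- purrr::pmap(list(apex, sigma), function(a, s) {
      peak_shape_fun(spec$peak_shape, a, s)
    })
    # ground-truth area by dense numeric integration of each noiseless shape
    area <- purrr::pmap_dbl(list(shapes, apex, sigma, height),
      function(f, a, s, h) {
        tt <- seq(a - 10 * s, a + 14 * s, length.out = 4001)
        h * trapz(tt, f(tt))
      }
    )
  } else {
    apex <- sigma <- height <- area <- double()
    shapes <- list()
  }

  signal_at <- function(t) {
    y <- rep(0, length(t))
    for (i in seq_along(shapes)) y <- y + height[i] * shapes[[i]](t)
    y
  }
  drift_at <- function(t) {
    spec$baseline_drift * (sin(2 * pi * (t - rt0) / span) + 0.3 * (t - rt0) / span)
  }

  render <- function(rate, lag, scale = 1, noise_sd = spec$noise_sd) {
    step <- 1 / (60 * rate)
    tms <- seq(rt0 - 0.5, rt1 + 0.5, by = step) # MS-axis times
    y <- scale * (signal_at(tms) + drift_at(tms)) + rnorm(length(tms), 0, noise_sd)
    tibble(time = tms - lag, intensity = y)
  }

  cad <- render(spec$cad_rate, lag_cad)
  pda <- render(10, lag_pda, scale = 0.8)
  bpi <- render(spec$ms_rate, 0, scale = 50, noise_sd = spec$noise_sd * 50)
  chromatograms <- bind_rows(
    mutate(cad, detector_id = "CAD", .before = 1),
    mutate(pda, detector_id = "PDA", .before = 1),
    mutate(bpi, detector_id = "BPI", .before = 1)
  )

  # features: shape-correlated majors + shifted decoys, XICs on the MS axis
  n_majors <- count_range(n, spec$n_majors_per_peak)
  n_decoys <- count_range(n, spec$n_decoys_per_peak)
  feats <- list()
  truth_feats <- list()
  fid <- 0L
  ms_step <- 1 / (60 * spec$ms_rate)
  for (i in seq_len(n)) {
    fwhm <- 2 * sqrt(2 * log(2)) * sigma[i]
    window <- max(6 * sigma[i], 0.5)
    grid <- seq(apex[i] - window, apex[i] + window, by = ms_step)
    for (j in seq_len(n_majors[i])) {
      fid <- fid + 1L
      scale <- 10^runif(1, 2, 5) # MS counts differ from CAD by orders of magnitude
      y <- scale * shapes[[i]](grid)
      y <- y + rnorm(length(y), 0, spec$major_noise_sd_frac * max(y))
      feats[[fid]] <- tibble(
        feature_id = fid, mode = spec$mode,
        mz = round(runif(1, 150, 1200), 4),
        rt_apex = grid[which.max(y)], height = max(y),
        xic = list(tibble(time = grid, intensity = y))
      )
      truth_feats[[fid]] <- tibble(feature_id = fid, parent_peak = i,
                                   is_major = TRUE)
    }
    for (j in seq_len(n_decoys[i])) {
      fid <- fid + 1L
      shift <- sample(c(-1, 1), 1) *
        (spec$decoy_shift_min_fwhm + runif(1)) * fwhm
      dm <- apex[i] + shift
      ds <- sigma[i] * runif(1, 0.7, 1.3)
      dshape <- peak_shape_fun("gaussian", dm, ds)
      scale <- 10^runif(1, 2, 5)
      dgrid <- seq(dm - max(6 * ds, 0.5), dm + max(6 * ds, 0.5), by = ms_step)
      y <- scale * dshape(dgrid)
      y <- y + rnorm(length(y), 0, spec$major_noise_sd_frac * max(y))
      feats[[fid]] <- tibble(
        feature_id = fid, mode = spec$mode,
        mz = round(runif(1, 150, 1200), 4),
        rt_apex = dgrid[which.max(y)], height = max(y),
        xic = list(tibble(time = dgrid, intensity = y))
      )
      truth_feats[[fid]] <- tibble(feature_id = fid, parent_peak = i,
                                   is_major = FALSE)
    }
  }
  features <- purrr::list_rbind(feats)
  if (is.null(features) || fid == 0L) {
    features <- tibble(feature_id = integer(), mode = character(),
                       mz = double(), rt_apex = double(), height = double(),
                       xic = list())
  }
  truth_features <- purrr::list_rbind(truth_feats)
  if (is.null(truth_features) || fid == 0L) {
    truth_features <- tibble(feature_id = integer(), parent_peak = integer(),
                             is_major = logical())
  }

  annotations <- simulate_annotations(spec, truth_features)
  network <- simulate_network(features, truth_features)

  list(
    chromatograms = chromatograms,
    features = features,
    annotations = annotations,
    network = network,
    truth = list(
      peaks = tibble(peak = seq_len(n), apex = apex, sigma = sigma,
                     height = height, area = area),
      features = truth_features,
      species_peaks = attr(annotations, "species_peaks")
    )
  )
}

npc_catalog <- function() {
  tribble(
    ~npc_pathway, ~npc_superclass, ~npc_class,
    "Terpenoids", "Triterpenoids", "Oleanane triterpenoids",
    "Terpenoids", "Triterpenoids", "Ursane triterpenoids",
    "Terpenoids", "Monoterpenoids", "Iridoid monoterpenoids",
    "Shikimates and Phenylpropanoids", "Phenylpropanoids (C6-C3)", "Cinnamic acids",
    "Shikimates and Phenylpropanoids", "Flavonoids", "Flavonols",
    "Polyketides", "Xanthones", "Simple xanthones",
    "Alkaloids", "Tryptophan alkaloids", "Simple indole alkaloids",
    "Fatty acids", "Fatty Acids and Conjugates", "Unsaturated fatty acids"
  )
}

simulate_annotations <- function(spec, truth_features) {
  cat_tbl <- npc_catalog()
  n <- spec$n_peaks
  species_peaks <- if (n > 0) {
    sort(sample(seq_len(n), size = round(spec$frac_species_peaks * n)))
  } else {
    integer()
  }
  peak_cat <- if (n > 0) sample(nrow(cat_tbl), n, replace = TRUE,
                                prob = c(25, 15, 12, 10, 8, 15, 8, 7)) else integer()
  peak_mf <- sprintf("C%dH%dO%d", sample(10:40, max(n, 1), replace = TRUE),
                     sample(12:60, max(n, 1), replace = TRUE),
                     sample(1:12, max(n, 1), replace = TRUE))

  rows <- purrr::pmap(truth_features, function(feature_id, parent_peak,
                                               is_major) {
    if (is_major) {
      at_species <- parent_peak %in% species_peaks
      ci <- peak_cat[parent_peak]
      tibble(
        feature_id = feature_id, rank = 1L,
        structure_id = sprintf("STRUCT-P%02d-%s", parent_peak,
                               if (at_species) "SP" else "GN"),
        molecular_formula = peak_mf[parent_peak],
        npc_pathway = cat_tbl$npc_pathway[ci],
        npc_superclass = cat_tbl$npc_superclass[ci],
        npc_class = cat_tbl$npc_class[ci],
        taxonomic_distance_score = if (at_species) 0.9 else 0.8,
        final_score = round(runif(1, 0.5, 1.05), 3),
        closest_organism = if (at_species) "Species alpha" else
          "Species beta (same genus)",
        taxon_level = if (at_species) "species" else "genus"
      )
    } else {
      ci <- sample(nrow(cat_tbl), 1L)
      tibble(
        feature_id = feature_id, rank = 1L,
        structure_id = sprintf("STRUCT-D%04d", feature_id),
        molecular_formula = sprintf("C%dH%dO%d", sample(8:35, 1),
                                    sample(10:50, 1), sample(1:10, 1)),
        npc_pathway = cat_tbl$npc_pathway[ci],
        npc_superclass = cat_tbl$npc_superclass[ci],
        npc_class = cat_tbl$npc_class[ci],
        taxonomic_distance_score = sample(c(0.6, 0.3), 1),
        final_score = round(runif(1, 0.05, 0.9), 3),
        closest_organism = "Species gamma (distant)",
        taxon_level = sample(c("family", "order", "class", "none"), 1)
      )
    }
  })
  out <- purrr::list_rbind(rows)
  if (is.null(out) || nrow(truth_features) == 0L) {
    out <- tibble(
      feature_id = integer(), rank = integer(), structure_id = character(),
      molecular_formula = character(), npc_pathway = character(),
      npc_superclass = character(), npc_class = character(),
      taxonomic_distance_score = double(), final_score = double(),
      closest_organism = character(), taxon_level = character()
    )
  }
  attr(out, "species_peaks") <- species_peaks
  out
}

simulate_network <- function(features, truth_features) {
  if (nrow(features) == 0L) {
    return(network_from_tables(tibble(feature_id = integer()),
                               tibble(from = integer(), to = integer())))
  }
  nodes <- select(features, feature_id, mz, rt_apex)
  edges <- truth_features |>
    group_by(.data$parent_peak) |>
    filter(n() > 1L) |>
    reframe(from = feature_id[-n()], to = feature_id[-1L]) |>
    transmute(from, to, type = "ms2", weight = round(runif(n(), 0.6, 1), 3))
  network_from_tables(nodes, edges)
}

#' Write a simulated bundle to disk
#'
#' Serializes a [simulate_extract()] bundle into the canonical exchange
#' files: a chromatogram-only mzML, tab-separated feature and annotation
#' tables, a GraphML network and a ground-truth JSON. Everything written
#' is readable back by the package's readers.
#'
#' @param bundle Output of [simulate_extract()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mzml = file.path(dir, "chromatograms.mzML"),
    features = file.path(dir, "features.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    network = file.path(dir, "network.graphml"),
    truth = file.path(dir, "truth.json")
  )
  write_fixture_mzml(bundle$chromatograms, paths["mzml"])
  write_features(bundle$features, paths["features"])
  write_annotations(bundle$annotations, paths["annotations"])
  write_network(bundle$network, paths["network"])
  jsonlite::write_json(
    list(peaks = bundle$truth$peaks, features = bundle$truth$features),
    paths["truth"],
    digits = NA
  )
  invisible(paths)
}
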