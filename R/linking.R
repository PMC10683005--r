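#' Linking configuration
#'
#' @param similarity_threshold Minimum peak-shape correlation for a feature
#'   to count as part of the major metabolome (default 0.8).
#' @param resample_rate Common rate (Hz) at which CAD and XIC segments are
#'   compared after normalization (default 2, the MS1 rate).
#' @return A list with class `link_config`.
#' @export
link_config <- function(similarity_threshold = 0.8, resample_rate = 2) {
  if (similarity_threshold <= 0 || similarity_threshold > 1) {
    abort("`similarity_threshold` must be in (0, 1].")
  }
  if (resample_rate <= 0) abort("`resample_rate` must be > 0.")
  structure(
    list(
      similarity_threshold = similarity_threshold,
      resample_rate = resample_rate
    ),
    class = "link_config"
  )
}

#' Assign features to enveloping CAD peaks
#'
#' A feature is a candidate of the unique CAD peak whose
#' `[left_bound, right_bound]` interval contains its apex retention time.
#' A feature whose apex sits exactly on a boundary shared by two peaks is
#' assigned to the earlier peak (deterministic tie-break); features outside
#' every peak are unassigned (`peak_id` `NA`).
#'
#' @param features Feature tibble with `feature_id` and `rt_apex` (minutes),
#'   on the same (aligned) time axis as the peaks.
#' @param peaks Peak tibble from [detect_peaks()].
#' @return A tibble `feature_id`, `peak_id` (`NA` when unassigned).
#' @export
assign_candidates <- function(features, peaks) {
  assignment <- purrr::map_int(features$rt_apex, function(rt) {
    hit <- which(peaks$left_bound <= rt & rt <= peaks$right_bound)
    if (length(hit) == 0L) NA_integer_ else as.integer(peaks$peak_id[min(hit)])
  })
  tibble(feature_id = features$feature_id, peak_id = assignment)
}

#' Normalize a CAD/XIC segment pair over a peak
#'
#' Crops both traces to the peak's bound interval (the region between the
#' CAD peak's minima), maps time affinely onto `[0, 1]`, min-max scales each
#' segment's intensity to `[0, 1]` (a constant segment maps to all zeros —
#' it carries no shape information), and resamples both onto the common
#' grid. Intensity normalization makes shapes comparable between compounds
#' whose MS response differs by orders of magnitude from the CAD response.
#'
#' @param cad_segment,xic_segment Trace tibbles covering (or extended to)
#'   the peak interval; values outside a trace's span are taken from its
#'   nearest edge.
#' @param peak One-row peak tibble (needs `left_bound`, `right_bound`).
#' @param rate Comparison rate in Hz over the original time scale.
#' @return A list of two normalized trace tibbles (`cad`, `xic`) on a shared
#'   unit-interval grid.
#' @export
normalize_pair <- function(cad_segment, xic_segment, peak, rate = 2) {
  lb <- peak$left_bound
  rb <- peak$right_bound
  if (!is.finite(lb) || !is.finite(rb) || rb <= lb) {
    abort("peak bounds do not define a nonempty interval.")
  }
  n <- max(3L, as.integer(round((rb - lb) * 60 * rate)) + 1L)
  u <- seq(0, 1, length.out = n)
  grid <- lb + u * (rb - lb)
  crop1 <- function(tr) {
    validate_trace(tr)
    y <- approx(tr$time, tr$intensity, xout = grid, rule = 2)$y
    rng <- range(y)
    y <- if (rng[2] > rng[1]) (y - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
    tibble(time = u, intensity = y)
  }
  list(cad = crop1(cad_segment), xic = crop1(xic_segment))
}

#' Peak-shape similarity of two normalized segments
#'
#' Pairs each point of the shorter trace with the temporally closest point
#' of the longer one (ties resolved to the earlier point) and returns the
#' Pearson correlation of the paired intensities — the "closest"-point
#' chromatogram comparison. When both traces share a grid, the pairing is
#' the identity. Zero-variance paired vectors return 0.
#'
#' @param a,b Trace tibbles with at least 3 points each.
#' @return Correlation in `[-1, 1]`.
#' @export
shape_similarity <- function(a, b) {
  validate_trace(a)
  validate_trace(b)
  if (nrow(a) < 3L || nrow(b) < 3L) {
    abort("shape_similarity() needs at least 3 points per trace.")
  }
  if (nrow(a) <= nrow(b)) {
    short <- a; long <- b
  } else {
    short <- b; long <- a
  }
  # closest-point pairing; on exact ties the earlier (smaller-time) point
  # of the longer trace wins because which.min() keeps the first minimum
  idx <- purrr::map_int(short$time, function(t0) which.min(abs(long$time - t0)))
  x <- short$intensity
  y <- long$intensity[idx]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Classify features as major or minor by peak shape
#'
#' For every feature assigned to a CAD peak (apex containment), computes the
#' peak-shape similarity between the feature's XIC and the CAD trace over
#' the peak's bound interval on normalized segments, and flags the feature
#' `major` when the similarity reaches the threshold. Features outside all
#' peaks are `minor` by default, with `peak_id` and `similarity` `NA`.
#' Every feature appears in exactly one link row.
#'
#' @param features Feature tibble (`feature_id`, `rt_apex`, `xic` list
#'   column of trace tibbles).
#' @param peaks Peak tibble from [detect_peaks()].
#' @param cad_trace The pretreated CAD trace the peaks were detected on.
#' @param config A [link_config()].
#' @return A link tibble: `feature_id`, `peak_id`, `similarity`,
#'   `status_shape` (`"major"`/`"minor"`).
#' @export
link_features <- function(features, peaks, cad_trace,
                          config = link_config()) {
  validate_trace(cad_trace)
  cand <- assign_candidates(features, peaks)
  sims <- purrr::map2_dbl(
    seq_len(nrow(features)), cand$peak_id,
    function(i, pid) {
      if (is.na(pid)) return(NA_real_)
      peak <- peaks[peaks$peak_id == pid, ]
      seg <- normalize_pair(cad_trace, features$xic[[i]], peak,
                            rate = config$resample_rate)
      shape_similarity(seg$cad, seg$xic)
    }
  )
  tibble(
    feature_id = features$feature_id,
    peak_id = cand$peak_id,
    similarity = sims,
    status_shape = if_else(
      !is.na(sims) & sims >= config$similarity_threshold, "major", "minor"
    )
  )
}
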