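#' Construct a detector trace
#'
#' A trace is the canonical one-dimensional detector signal used throughout
#' the package: a tibble with a `time` column (minutes, strictly increasing)
#' and an `intensity` column (detector units, finite). CAD, PDA, BPI and
#' per-feature XIC signals all use this representation.
#'
#' @param time Numeric vector of retention times in minutes, strictly
#'   increasing, length at least 2.
#' @param intensity Numeric vector of intensities, same length as `time`,
#'   all values finite.
#' @return A tibble with columns `time` and `intensity`.
#' @examples
#' trace_tbl(c(0, 0.5, 1), c(0, 1, 0))
#' @export
trace_tbl <- function(time, intensity) {
  out <- tibble(time = as.double(time), intensity = as.double(intensity))
  validate_trace(out)
  out
}

validate_trace <- function(trace, arg = "trace") {
  if (!is.data.frame(trace) || !all(c("time", "intensity") %in% names(trace))) {
    abort(sprintf("`%s` must be a data frame with columns `time` and `intensity`.", arg))
  }
  if (nrow(trace) < 2L) {
    abort(sprintf("`%s` must contain at least 2 points.", arg))
  }
  if (!all(is.finite(trace$time)) || !all(is.finite(trace$intensity))) {
    abort(sprintf("`%s` contains non-finite times or intensities.", arg))
  }
  if (any(diff(trace$time) <= 0)) {
    abort(sprintf("`%s` times must be strictly increasing.", arg))
  }
  invisible(trace)
}

# uniform-grid check: spacing deviations below a relative tolerance of the
# median step are treated as uniform (guards against float jitter only)
is_uniform <- function(trace, rel_tol = 1e-6) {
  dt <- diff(trace$time)
  h <- median(dt)
  h > 0 && max(abs(dt - h)) <= rel_tol * h
}

# ensure a uniform grid at the trace's own native rate
resample_native <- function(trace) {
  if (is_uniform(trace)) return(trace)
  resample_trace(trace, 1 / (60 * median(diff(trace$time))))
}

uniform_step <- function(trace) {
  if (!is_uniform(trace)) {
    abort("trace is not uniformly sampled; call resample_trace() first.")
  }
  median(diff(trace$time))
}

#' Extract one detector's trace from a chromatogram set
#'
#' @param chromatograms A chromatogram set tibble with columns `detector_id`,
#'   `time`, `intensity` (as returned by [read_chromatograms()]).
#' @param detector Detector label, e.g. `"CAD"`, `"PDA"`, `"BPI_pos"`.
#' @return A trace tibble (`time`, `intensity`).
#' @export
get_trace <- function(chromatograms, detector) {
  out <- chromatograms |>
    filter(detector_id == detector) |>
    select(time, intensity)
  if (nrow(out) == 0L) {
    abort(sprintf("no `%s` trace in this chromatogram set (CAD-dependent steps refuse to run without one).", detector))
  }
  validate_trace(out)
  out
}
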