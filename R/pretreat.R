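#' Pretreatment configuration
#'
#' Bundles the signal-pretreatment parameters. Detector lags map the PDA and
#' CAD time axes onto the MS axis: the MS signal arrives 0.090 min after the
#' PDA and 0.055 min after the CAD (post-column split geometry), so those
#' traces are delayed by the corresponding lag before any cross-detector
#' comparison. Denoising keeps the lowest fraction of Fourier components;
#' sharpening subtracts a scaled second derivative (classic even-derivative
#' resolution enhancement), with the weight derived from a nominal peak
#' width `w` as `k2 = (w / 4)^2` unless given explicitly.
#'
#' @param lag_pda_to_ms Lag applied to the PDA trace, minutes (default 0.090).
#' @param lag_cad_to_ms Lag applied to the CAD trace, minutes (default 0.055).
#' @param fourier_component_fraction Fraction of low-frequency Fourier
#'   components retained by [denoise_fft()], in (0, 1] (default 0.01).
#' @param peak_width Nominal chromatographic peak width in minutes used to
#'   scale the sharpening weight (default 0.1).
#' @param sharpen_k2 Second-derivative weight; default `(peak_width / 4)^2`.
#' @param sharpen_k4 Fourth-derivative weight (default 0).
#' @param resample_rate Target uniform sampling rate in Hz (default 2,
#'   matching the MS1 acquisition rate).
#' @return A list with class `pretreat_config`.
#' @export
pretreat_config <- function(lag_pda_to_ms = 0.090,
                            lag_cad_to_ms = 0.055,
                            fourier_component_fraction = 0.01,
                            peak_width = 0.1,
                            sharpen_k2 = (peak_width / 4)^2,
                            sharpen_k4 = 0,
                            resample_rate = 2) {
  if (resample_rate <= 0) abort("`resample_rate` must be > 0.")
  if (fourier_component_fraction <= 0 || fourier_component_fraction > 1) {
    abort("`fourier_component_fraction` must be in (0, 1].")
  }
  if (sharpen_k2 < 0 || sharpen_k4 < 0) abort("sharpening weights must be >= 0.")
  structure(
    list(
      lag_pda_to_ms = lag_pda_to_ms,
      lag_cad_to_ms = lag_cad_to_ms,
      fourier_component_fraction = fourier_component_fraction,
      peak_width = peak_width,
      sharpen_k2 = sharpen_k2,
      sharpen_k4 = sharpen_k4,
      resample_rate = resample_rate
    ),
    class = "pretreat_config"
  )
}

#' Shift a trace's time axis by a constant lag
#'
#' Maps a non-MS detector onto the MS time axis. Intensities are untouched.
#'
#' @param trace A trace tibble.
#' @param lag Shift in minutes, added to every time point.
#' @return The shifted trace.
#' @export
align_trace <- function(trace, lag) {
  validate_trace(trace)
  if (!is.finite(lag)) abort("`lag` must be finite.")
  mutate(trace, time = time + lag)
}

#' Fourier low-pass denoising
#'
#' Forward DFT, retention of the lowest `ceiling(fraction * N)` frequency
#' components (with their conjugate-symmetric partners; the DC component is
#' always kept), inverse DFT. A hard brick-wall filter with a single
#' parameter, matching FFT-component noise reduction as used for dense CAD
#' acquisitions.
#'
#' @param trace A uniformly sampled trace tibble.
#' @param component_fraction Fraction of components kept, in (0, 1].
#' @return The denoised trace on the same grid.
#' @export
denoise_fft <- function(trace, component_fraction = 0.01) {
  validate_trace(trace)
  if (component_fraction <= 0 || component_fraction > 1) {
    abort("`component_fraction` must be in (0, 1].")
  }
  if (!is_uniform(trace)) {
    abort("denoise_fft() requires a uniformly sampled trace; call resample_trace() first.")
  }
  y <- trace$intensity
  n <- length(y)
  k <- ceiling(component_fraction * n)
  if (k >= ceiling(n / 2)) {
    # all frequencies retained: identity
    return(trace)
  }
  f <- fft(y)
  keep <- rep(FALSE, n)
  keep[seq_len(k)] <- TRUE
  if (k >= 2L) keep[n - seq(2L, k) + 2L] <- TRUE
  f[!keep] <- 0
  mutate(trace, intensity = Re(fft(f, inverse = TRUE)) / n)
}

#' Even-derivative peak sharpening
#'
#' Returns `y - k2 * y'' + k4 * y''''` with derivatives taken by central
#' finite differences on the uniform grid (step in minutes); the first and
#' last two points fall back to one-sided (shifted-stencil) differences.
#' Subtracting a weighted second derivative narrows near-Gaussian peaks
#' while conserving their area (the integral of `y''` vanishes for a
#' decaying signal); undershoots below zero are expected and deliberately
#' not clipped, peak detection handles the baseline.
#'
#' @param trace A uniformly sampled trace tibble of length >= 5.
#' @param k2 Second-derivative weight (min^2), >= 0.
#' @param k4 Fourth-derivative weight (min^4), >= 0.
#' @return The sharpened trace.
#' @export
sharpen_derivative <- function(trace, k2, k4 = 0) {
  validate_trace(trace)
  if (nrow(trace) < 5L) abort("sharpen_derivative() needs at least 5 points.")
  h <- uniform_step(trace)
  y <- trace$intensity
  n <- length(y)

  d2 <- numeric(n)
  i <- 2:(n - 1)
  d2[i] <- (y[i - 1] - 2 * y[i] + y[i + 1]) / h^2
  d2[1] <- (y[1] - 2 * y[2] + y[3]) / h^2
  d2[n] <- (y[n] - 2 * y[n - 1] + y[n - 2]) / h^2

  d4 <- numeric(n)
  i <- 3:(n - 2)
  d4[i] <- (y[i - 2] - 4 * y[i - 1] + 6 * y[i] - 4 * y[i + 1] + y[i + 2]) / h^4
  d4[1] <- (y[1] - 4 * y[2] + 6 * y[3] - 4 * y[4] + y[5]) / h^4
  d4[2] <- d4[1]
  d4[n] <- (y[n] - 4 * y[n - 1] + 6 * y[n - 2] - 4 * y[n - 3] + y[n - 4]) / h^4
  d4[n - 1] <- d4[n]

  mutate(trace, intensity = y - k2 * d2 + k4 * d4)
}

#' Resample a trace to a uniform rate
#'
#' Builds a uniform grid spanning the trace at `1 / (60 * rate)` minute
#' spacing and linearly interpolates intensities onto it. Queries outside
#' the original span (which arise when two detectors' grids are unioned)
#' take the nearest edge value.
#'
#' @param trace A trace tibble.
#' @param rate Target rate in Hz (> 0). 2 Hz matches the MS1 scan rate.
#' @param from,to Optional grid limits in minutes; default to the trace span.
#' @return A uniformly sampled trace.
#' @export
resample_trace <- function(trace, rate = 2, from = NULL, to = NULL) {
  validate_trace(trace)
  if (rate <= 0) abort("`rate` must be > 0.")
  from <- from %||% trace$time[1]
  to <- to %||% trace$time[nrow(trace)]
  step <- 1 / (60 * rate)
  grid <- seq(from, to, by = step)
  # rule = 2: constant extrapolation beyond the measured span
  y <- approx(trace$time, trace$intensity, xout = grid, rule = 2)$y
  tibble(time = grid, intensity = y)
}

#' Full pretreatment of one trace
#'
#' Applies the canonical order: lag alignment, FFT denoising on the native
#' uniform grid, derivative sharpening on the native grid, then resampling
#' to the target rate. All detectors (CAD, PDA, BPI) run through the same
#' chain so that their peak shapes stay comparable.
#'
#' @param trace A trace tibble.
#' @param lag Detector lag in minutes (0 for MS-axis traces).
#' @param config A [pretreat_config()].
#' @param resample Resample to `config$resample_rate` after sharpening
#'   (default `TRUE`). Set `FALSE` to keep the native (denser) grid, e.g.
#'   for peak detection at full CAD resolution.
#' @return The pretreated trace.
#' @export
pretreat_trace <- function(trace, lag = 0, config = pretreat_config(),
                           resample = TRUE) {
  out <- align_trace(trace, lag)
  if (!is_uniform(out)) {
    native_rate <- 1 / (60 * median(diff(out$time)))
    out <- resample_trace(out, native_rate)
  }
  out <- denoise_fft(out, config$fourier_component_fraction)
  out <- sharpen_derivative(out, config$sharpen_k2, config$sharpen_k4)
  if (resample) out <- resample_trace(out, config$resample_rate)
  out
}

#' Pretreat every trace of a chromatogram set
#'
#' Applies [pretreat_trace()] per detector with the detector's configured
#' lag (CAD and PDA are delayed onto the MS axis; MS-derived traces get no
#' lag).
#'
#' @param chromatograms Chromatogram set tibble (`detector_id`, `time`,
#'   `intensity`).
#' @param config A [pretreat_config()].
#' @param resample See [pretreat_trace()].
#' @return A chromatogram set tibble of pretreated traces.
#' @export
pretreat_chromatograms <- function(chromatograms, config = pretreat_config(),
                                   resample = TRUE) {
  lags <- c(CAD = config$lag_cad_to_ms, PDA = config$lag_pda_to_ms)
  chromatograms |>
    group_by(detector_id) |>
    group_modify(function(tr, key) {
      lag <- unname(lags[key$detector_id])
      if (is.na(lag)) lag <- 0
      pretreat_trace(select(tr, time, intensity), lag, config, resample)
    }) |>
    ungroup()
}
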