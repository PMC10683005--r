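#' Robust noise level of a trace
#'
#' Estimates the local noise standard deviation from the first difference of
#' the intensities: `1.4826 * MAD(diff(y)) / sqrt(2)`. Differencing removes
#' slow baseline and peak structure; the MAD makes the estimate robust to
#' the peaks that remain in the difference, and the `sqrt(2)` undoes the
#' variance doubling of differencing.
#'
#' @param trace A trace tibble of length >= 10.
#' @return A one-row tibble with columns `level` (trace units) and `method`.
#' @export
estimate_noise <- function(trace) {
  validate_trace(trace)
  if (nrow(trace) < 10L) abort("estimate_noise() needs at least 10 points.")
  level <- mad(diff(trace$intensity)) / sqrt(2)
  tibble(level = level, method = "diff_mad")
}

#' Detect peaks on a pretreated CAD trace
#'
#' Apexes are local maxima (leftmost sample of a plateau) whose height above
#' a per-peak linear baseline is at least `min_snr` times the robust noise
#' level; bounds extend from each apex to the nearest local minimum on each
#' side (or the trace ends). Peaks narrower than `min_width` are discarded.
#' Works on the sharpened, denoised signal, where simple one-dimensional
#' rules suffice.
#'
#' @param trace A pretreated, uniformly sampled trace tibble.
#' @param min_snr Minimum apex height over noise level (default 5).
#' @param min_width Minimum peak width (bound to bound) in minutes
#'   (default 0.05).
#' @param noise_level Noise level for the SNR gate; defaults to
#'   [estimate_noise()] on `trace`. Pass the raw-trace noise when detecting
#'   on a denoised signal, so the gate reflects the detector, not the
#'   filter residue.
#' @return A tibble of peaks: `peak_id`, `apex_time`, `left_bound`,
#'   `right_bound`, `height` (above the local baseline) and `area`
#'   (baseline-subtracted trapezoidal, units x min), sorted by `apex_time`.
#'   Zero rows when nothing qualifies.
#' @export
detect_peaks <- function(trace, min_snr = 5, min_width = 0.05,
                         noise_level = NULL) {
  validate_trace(trace)
  uniform_step(trace) # errors on nonuniform input
  t <- trace$time
  y <- trace$intensity
  n <- length(y)
  noise <- noise_level %||% estimate_noise(trace)$level

  empty <- tibble(
    peak_id = integer(), apex_time = double(), left_bound = double(),
    right_bound = double(), height = double(), area = double()
  )
  if (n < 3L) return(empty)

  # leftmost-of-plateau local maxima: strictly above the left neighbour,
  # not below the right neighbour
  apex_idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(apex_idx) == 0L) return(empty)

  rows <- purrr::map(apex_idx, function(a) {
    l <- a
    while (l > 1L && y[l - 1L] < y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] < y[r]) r <- r + 1L
    base_apex <- y[l] + (y[r] - y[l]) * (t[a] - t[l]) / (t[r] - t[l])
    tibble(
      apex_idx = a, left_idx = l, right_idx = r,
      apex_time = t[a], left_bound = t[l], right_bound = t[r],
      height = y[a] - base_apex
    )
  }) |>
    purrr::list_rbind() |>
    filter(
      height >= min_snr * noise,
      right_bound - left_bound >= min_width
    )
  if (nrow(rows) == 0L) return(empty)

  rows |>
    arrange(apex_time) |>
    mutate(
      peak_id = row_number(),
      area = purrr::map2_dbl(
        .data$left_idx, .data$right_idx,
        function(l, r) baseline_subtracted_area(t, y, l, r)
      )
    ) |>
    select(peak_id, apex_time, left_bound, right_bound, height, area)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

baseline_subtracted_area <- function(t, y, l, r) {
  seg <- l:r
  raw <- trapz(t[seg], y[seg])
  base <- trapz(t[c(l, r)], y[c(l, r)])
  a <- raw - base
  if (a < 0) {
    warn("negative baseline-subtracted peak area clamped to 0.")
    a <- 0
  }
  a
}

#' Baseline-subtracted trapezoidal area of one peak
#'
#' Integrates the trace between the peak's bounds and subtracts the linear
#' baseline through the two boundary intensities. Negative results (possible
#' on pathological baselines) are clamped to 0 with a warning.
#'
#' @param trace A trace tibble whose span covers the peak bounds.
#' @param peak A one-row peak tibble (or list) with `left_bound` and
#'   `right_bound` in minutes.
#' @return The area in trace units x min.
#' @export
integrate_peak <- function(trace, peak) {
  validate_trace(trace)
  lb <- peak$left_bound
  rb <- peak$right_bound
  t <- trace$time
  if (lb < t[1] || rb > t[length(t)] || lb >= rb) {
    abort("peak bounds fall outside the trace span.")
  }
  inside <- which(t >= lb & t <= rb)
  # interpolated endpoints so bounds need not sit on grid points
  xs <- unique(c(lb, t[inside], rb))
  ys <- approx(t, trace$intensity, xout = xs, rule = 2)$y
  raw <- trapz(xs, ys)
  base <- trapz(c(lb, rb), ys[c(1L, length(ys))])
  a <- raw - base
  if (a < 0) {
    warn("negative baseline-subtracted peak area clamped to 0.")
    a <- 0
  }
  a
}
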