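test_that("lag alignment shifts times only and is invertible", {
  tr <- trace_tbl(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
  shifted <- align_trace(tr, 0.055)
  expect_equal(shifted$time, tr$time + 0.055)
  expect_identical(shifted$intensity, tr$intensity)
  expect_identical(align_trace(tr, 0), tr)
  back <- align_trace(align_trace(tr, 0.09), -0.09)
  expect_equal(back$time, tr$time, tolerance = 1e-12)
})

test_that("FFT denoising keeps DC, reconstructs sub-cutoff sinusoids, is identity at fraction 1", {
  n <- 1000
  t <- seq(0, (n - 1) / 120, by = 1 / 120)

  const <- trace_tbl(t, rep(3.7, n))
  expect_equal(denoise_fft(const, 0.01)$intensity, rep(3.7, n),
               tolerance = 1e-9)

  # 3 cycles over the window sits below the ceil(0.01 * 1000) = 10 component cutoff
  y <- sin(2 * pi * 3 * seq(0, n - 1) / n)
  sine <- trace_tbl(t, y)
  expect_lt(max(abs(denoise_fft(sine, 0.01)$intensity - y)), 1e-9)

  set.seed(5)
  noisy <- trace_tbl(t, rnorm(n))
  out <- denoise_fft(noisy, 0.05)
  expect_lt(var(out$intensity), var(noisy$intensity))

  expect_lt(max(abs(denoise_fft(noisy, 1)$intensity - noisy$intensity)), 1e-9)
})

test_that("FFT denoising refuses nonuniform sampling", {
  tr <- trace_tbl(c(0, 0.1, 0.3, 0.35, 0.6), rep(1, 5))
  expect_error(denoise_fft(tr), "resample")
})

test_that("derivative sharpening narrows a Gaussian, keeps apex and area, and is linear", {
  sigma <- 0.05
  tr <- gauss_trace(1, sigma, 1 / (sigma * sqrt(2 * pi)), span = c(0, 2),
                    rate = 2)
  k2 <- sigma^2 / 4
  out <- sharpen_derivative(tr, k2, 0)

  expect_lt(fwhm_numeric(out), fwhm_numeric(tr))
  step <- diff(tr$time)[1]
  expect_lte(abs(out$time[which.max(out$intensity)] -
                   tr$time[which.max(tr$intensity)]), step)
  a_in <- trapz_oracle(tr$time, tr$intensity)
  a_out <- trapz_oracle(out$time, out$intensity)
  expect_lt(abs(a_out - a_in) / a_in, 0.005)

  zero <- trace_tbl(tr$time, rep(0, nrow(tr)))
  expect_equal(sharpen_derivative(zero, k2, 1)$intensity, zero$intensity)

  set.seed(8)
  y1 <- rnorm(50)
  y2 <- rnorm(50)
  t50 <- seq_len(50) / 120
  lhs <- sharpen_derivative(trace_tbl(t50, 2 * y1 - 3 * y2), 0.01, 0.001)
  rhs_a <- sharpen_derivative(trace_tbl(t50, y1), 0.01, 0.001)
  rhs_b <- sharpen_derivative(trace_tbl(t50, y2), 0.01, 0.001)
  expect_equal(lhs$intensity, 2 * rhs_a$intensity - 3 * rhs_b$intensity,
               tolerance = 1e-9)

  expect_error(sharpen_derivative(trace_tbl(1:4 / 60, rep(1, 4)), 0.01),
               "5 points")
})

test_that("resampling is exact on linear ramps and on matching grids, and extends edges", {
  t <- seq(0, 3, by = 1 / 120) # already an exact 2 Hz grid
  ramp <- trace_tbl(t, t)
  out <- resample_trace(ramp, 2)
  expect_equal(out$time, t, tolerance = 1e-12)
  expect_equal(out$intensity, t, tolerance = 1e-12)

  out5 <- resample_trace(ramp, 5)
  expect_equal(out5$intensity, out5$time, tolerance = 1e-12)

  wide <- resample_trace(ramp, 2, from = -0.5, to = 3.5)
  expect_equal(wide$intensity[wide$time < 0], rep(0, sum(wide$time < 0)))
  expect_equal(wide$intensity[wide$time > 3],
               rep(3, sum(wide$time > 3)))
})

test_that("the same pretreatment chain runs on every detector of a set", {
  b <- simulate_extract(fixture_spec(n_peaks = 3, rt_span = c(0, 4), seed = 2))
  pre <- pretreat_chromatograms(b$chromatograms, pretreat_config())
  expect_setequal(unique(pre$detector_id), c("CAD", "PDA", "BPI"))
  for (det in c("CAD", "PDA", "BPI")) {
    tr <- get_trace(pre, det)
    expect_true(all(diff(tr$time) > 0))
    # all detectors resampled to the common 2 Hz grid spacing
    expect_equal(median(diff(tr$time)), 1 / 120, tolerance = 1e-9)
  }
  # CAD was delayed onto the MS axis
  cad_raw <- get_trace(b$chromatograms, "CAD")
  cad_pre <- get_trace(pre, "CAD")
  expect_equal(cad_pre$time[1], cad_raw$time[1] + 0.055, tolerance = 1e-9)
})
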