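test_that("the generator is deterministic under a fixed seed", {
  spec <- fixture_spec(n_peaks = 3, rt_span = c(0, 4), seed = 7)
  a <- simulate_extract(spec)
  b <- simulate_extract(spec)
  expect_identical(a$chromatograms, b$chromatograms)
  expect_identical(a$features, b$features)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$peaks, b$truth$peaks)
})

test_that("the generator honors its own spec: peak, feature and score structure", {
  spec <- fixture_spec(n_peaks = 6, rt_span = c(0, 7),
                       n_majors_per_peak = 2, n_decoys_per_peak = 3,
                       seed = 13)
  b <- simulate_extract(spec)
  expect_identical(nrow(b$truth$peaks), 6L)
  expect_identical(nrow(b$features), 6L * 5L)
  per_peak <- table(b$truth$features$parent_peak)
  expect_true(all(per_peak == 5))
  expect_identical(sum(b$truth$features$is_major), 12L)
  # majors of species-level peaks carry the species taxonomic score
  majors <- b$truth$features$feature_id[b$truth$features$is_major]
  sc <- b$annotations$taxonomic_distance_score[
    b$annotations$feature_id %in% majors & b$annotations$rank == 1
  ]
  expect_true(all(sc %in% c(0.9, 0.8)))
  # planted apexes keep at least 4 sigma separation
  pk <- b$truth$peaks
  expect_true(all(diff(pk$apex) >= 4 * pmax(head(pk$sigma, -1),
                                            tail(pk$sigma, -1))))
})

test_that("an infeasibly crowded window is rejected", {
  expect_error(fixture_spec(n_peaks = 50, rt_span = c(0, 2)), "spacing")
})

test_that("the noiseless, decoy-free limit classifies every feature as a shape major", {
  spec <- fixture_spec(
    n_peaks = 4, rt_span = c(0, 5), n_majors_per_peak = 2,
    n_decoys_per_peak = 0, major_noise_sd_frac = 0, baseline_drift = 0,
    noise_sd = 0, seed = 5
  )
  b <- simulate_extract(spec)
  cad_aligned <- align_trace(get_trace(b$chromatograms, "CAD"), 0.055)
  cad_sharp <- pretreat_trace(get_trace(b$chromatograms, "CAD"), 0.055,
                              resample = FALSE)
  peaks <- detect_peaks(cad_sharp)
  # every planted apex recovered (sharpening sidelobes may add tiny extras;
  # they carry no features and are ignored downstream)
  for (a in b$truth$peaks$apex) {
    expect_true(any(abs(peaks$apex_time - a) <= 1 / 3600))
  }
  links <- link_features(b$features, peaks, denoise_fft(cad_aligned, 0.01))
  expect_true(all(links$status_shape == "major"))
  expect_true(all(links$similarity >= 0.999))
})

test_that("an empty spec produces a flat-noise trace and empty tables", {
  b <- simulate_extract(fixture_spec(n_peaks = 0, rt_span = c(0, 2),
                                     seed = 1))
  expect_identical(nrow(b$features), 0L)
  expect_identical(nrow(b$annotations), 0L)
  cad <- get_trace(b$chromatograms, "CAD")
  expect_lt(max(abs(cad$intensity)), 10) # noise + drift only
})

test_that("written bundles are readable back and consistent with the truth", {
  b <- simulate_extract(fixture_spec(n_peaks = 3, rt_span = c(0, 4),
                                     seed = 23))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(b, dir)
  expect_true(all(file.exists(paths)))

  feats <- read_features(paths[["features"]])
  expect_identical(nrow(feats), nrow(b$features))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(nrow(truth$features), nrow(feats))

  chroms <- read_chromatograms(paths[["mzml"]])
  cad_in <- get_trace(b$chromatograms, "CAD")
  cad_out <- get_trace(chroms, "CAD")
  expect_equal(cad_out$time, cad_in$time, tolerance = 1e-9)
  expect_equal(cad_out$intensity, cad_in$intensity, tolerance = 1e-9)

  ann <- read_annotations(paths[["annotations"]])
  expect_equal(as.data.frame(ann),
               as.data.frame(dplyr::arrange(b$annotations, feature_id, rank)),
               ignore_attr = TRUE)
})
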