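toy_peaks <- tibble::tibble(
  peak_id = 1:2, apex_time = c(1.0, 2.0),
  left_bound = c(0.8, 1.8), right_bound = c(1.2, 2.2),
  height = c(10, 20), area = c(1, 2)
)

feat <- function(id, rt) {
  tibble::tibble(
    feature_id = id, mode = "pos", mz = 100 + id, rt_apex = rt, height = 1,
    xic = list(trace_tbl(rt + c(-0.2, 0, 0.2), c(0, 1, 0)))
  )
}

test_that("candidate assignment is apex containment with an earlier-peak tie-break", {
  feats <- dplyr::bind_rows(feat(1L, 1.1), feat(2L, 1.5), feat(3L, 2.2))
  got <- assign_candidates(feats, toy_peaks)
  expect_identical(got$peak_id, c(1L, NA_integer_, 2L))

  touching <- toy_peaks
  touching$right_bound[1] <- 1.8 # shares the boundary with peak 2
  got2 <- assign_candidates(feat(9L, 1.8), touching)
  expect_identical(got2$peak_id, 1L)
})

test_that("all 128 features under one broad peak become its candidates", {
  big <- tibble::tibble(peak_id = 1L, apex_time = 5, left_bound = 4,
                        right_bound = 6, height = 100, area = 10)
  feats <- purrr::map(1:128, ~ feat(.x, 4 + 2 * .x / 129)) |>
    purrr::list_rbind()
  got <- assign_candidates(feats, big)
  expect_identical(sum(got$peak_id == 1L, na.rm = TRUE), 128L)
})

test_that("segment normalization is identity-safe, scale-invariant, and zeroes constants", {
  peak <- list(left_bound = 0.8, right_bound = 1.2)
  cad <- trace_tbl(seq(0.7, 1.3, by = 1 / 120),
                   gauss(seq(0.7, 1.3, by = 1 / 120), 1, 0.05, 10))
  same <- normalize_pair(cad, cad, peak)
  expect_equal(same$cad, same$xic)
  expect_equal(range(same$cad$intensity), c(0, 1))
  expect_equal(range(same$cad$time), c(0, 1))

  scaled <- dplyr::mutate(cad, intensity = intensity * 3.7)
  pair <- normalize_pair(cad, scaled, peak)
  expect_equal(pair$cad$intensity, pair$xic$intensity, tolerance = 1e-12)

  const <- dplyr::mutate(cad, intensity = 2)
  pair2 <- normalize_pair(cad, const, peak)
  expect_identical(unique(pair2$xic$intensity), 0)
})

test_that("shape similarity matches a hand-computed Pearson and its invariances", {
  a <- trace_tbl(c(0, 0.5, 1), c(1, 2, 3))
  b <- trace_tbl(c(0, 0.5, 1), c(3, 2, 1))
  # Pearson of (1,2,3) vs (3,2,1) by hand: cov = -1, sds = 1 -> r = -1
  expect_equal(shape_similarity(a, b), -1, tolerance = 1e-12)
  expect_equal(shape_similarity(a, a), 1, tolerance = 1e-12)

  affine <- trace_tbl(a$time, 2.5 * a$intensity + 7)
  expect_equal(shape_similarity(a, affine), 1, tolerance = 1e-12)

  # symmetry on equal-length grids
  set.seed(21)
  x <- trace_tbl(seq(0, 1, length.out = 9), runif(9))
  y <- trace_tbl(seq(0, 1, length.out = 9), runif(9))
  expect_equal(shape_similarity(x, y), shape_similarity(y, x))

  flat <- trace_tbl(a$time, rep(1, 3))
  expect_identical(shape_similarity(a, flat), 0)

  expect_error(shape_similarity(trace_tbl(c(0, 1), c(0, 1)), a), "3 points")
})

test_that("min-max intensity scaling never changes the Pearson similarity", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    t <- seq(0, 1, length.out = n)
    y1 <- runif(n)
    y2 <- runif(n)
    scale01 <- function(v) (v - min(v)) / (max(v) - min(v))
    r_raw <- shape_similarity(trace_tbl(t, y1), trace_tbl(t, y2))
    r_scaled <- shape_similarity(trace_tbl(t, scale01(y1)),
                                 trace_tbl(t, scale01(y2)))
    expect_equal(r_scaled, r_raw, tolerance = 1e-9)
  }
})

test_that("classification thresholds majors, keeps peak context on near-misses, partitions features", {
  t <- seq(0.5, 2.5, by = 1 / 120)
  cad <- trace_tbl(t, gauss(t, 1, 0.08, 100) + gauss(t, 2, 0.08, 80))
  peaks <- detect_peaks(cad)
  feats <- dplyr::bind_rows(
    tibble::tibble(feature_id = 1L, mode = "pos", mz = 300, rt_apex = 1,
                   height = 5,
                   xic = list(trace_tbl(t, gauss(t, 1, 0.08, 5e4)))),
    tibble::tibble(feature_id = 2L, mode = "pos", mz = 400, rt_apex = 1.02,
                   height = 3,
                   xic = list(trace_tbl(t, gauss(t, 1.3, 0.08, 3e4)))),
    feat(3L, 0.2) # outside every peak
  )
  links <- link_features(feats, peaks, cad)
  expect_identical(nrow(links), nrow(feats)) # partition: one link per feature
  l1 <- links[links$feature_id == 1L, ]
  expect_identical(l1$status_shape, "major")
  expect_gte(l1$similarity, 0.8)
  l2 <- links[links$feature_id == 2L, ] # shifted: below threshold but linked
  expect_identical(l2$status_shape, "minor")
  expect_false(is.na(l2$peak_id))
  expect_false(is.na(l2$similarity))
  l3 <- links[links$feature_id == 3L, ]
  expect_identical(l3$status_shape, "minor")
  expect_true(is.na(l3$peak_id))
  expect_true(is.na(l3$similarity))
})

test_that("raising the threshold never increases the major count", {
  b <- simulate_extract(fixture_spec(n_peaks = 8, rt_span = c(0, 9),
                                     seed = 17))
  cad <- pretreat_trace(get_trace(b$chromatograms, "CAD"), 0.055,
                        resample = FALSE)
  peaks <- detect_peaks(cad)
  prev <- Inf
  for (thr in seq(0.5, 0.95, by = 0.15)) {
    links <- link_features(b$features, peaks, cad,
                           link_config(similarity_threshold = thr))
    n_major <- sum(links$status_shape == "major")
    expect_lte(n_major, prev)
    prev <- n_major
  }
})
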