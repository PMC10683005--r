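# shared small scenario: 3 peaks, 9 features, one peak left unannotated
reporting_scenario <- function() {
  peaks <- tibble::tibble(
    peak_id = 1:3, apex_time = c(1, 2, 3),
    left_bound = c(0.8, 1.8, 2.8), right_bound = c(1.2, 2.2, 3.2),
    height = c(10, 20, 30), area = c(20, 30, 50)
  )
  links <- tibble::tibble(
    feature_id = 1:9,
    peak_id = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, NA, NA),
    similarity = c(0.9, 0.85, 0.95, 0.9, 0.82, 0.9, 0.88, NA, NA),
    status_shape = c(rep("major", 7), "minor", "minor")
  )
  ann <- dplyr::bind_rows(
    ann_row(1L, 0.9, 0.8, structure = "S-A", pathway = "Terpenoids"),
    ann_row(2L, 0.9, 0.9, structure = "S-B", pathway = "Terpenoids"),
    ann_row(3L, 0.8, 0.7, structure = "S-C", pathway = "Polyketides"),
    ann_row(4L, 0.6, 0.2, structure = "S-D"),
    ann_row(5L, 0.6, 0.9, structure = "S-E"),
    # peak 3's features: no confident candidate
    ann_row(6L, 0.6, 0.1, structure = "S-F"),
    ann_row(8L, 0.3, 0.9, structure = "S-G", pathway = "Alkaloids"),
    ann_row(9L, 0.3, 0.9, structure = "S-H", pathway = "Alkaloids")
  )
  cas <- apply_filter_cascade(links, ann)
  list(peaks = peaks, links = links, ann = ann, cas = cas)
}

test_that("summary means match hand arithmetic and handle the empty case", {
  sc <- reporting_scenario()
  # no-filter stage: peaks 1,2,3 have {2,3,2} linked features -> mean 7/3 = 2.3
  st <- summarize_links(sc$cas$links, sc$ann, sc$peaks, "none")
  expect_identical(st$features_linked, 7L)
  expect_equal(st$mean_features_per_peak, 2.3)
  expect_identical(st$picked_features, 9L)
  expect_identical(st$picked_peaks, 3L)

  # 3-peak fixture with {2,3,4} linked features -> mean 3.0
  links2 <- tibble::tibble(
    feature_id = 1:9,
    peak_id = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
    similarity = 0.9, status_shape = "major"
  )
  st2 <- summarize_links(links2, sc$ann[0, ], sc$peaks, "none")
  expect_equal(st2$mean_features_per_peak, 3.0)

  none <- summarize_links(
    tibble::tibble(feature_id = 1L, peak_id = NA_integer_,
                   similarity = NA_real_, status_shape = "minor"),
    sc$ann[0, ], sc$peaks, "none"
  )
  expect_identical(none$features_linked, 0L)
  expect_true(is.na(none$mean_features_per_peak))
})

test_that("rounding of means is half-up at one decimal", {
  peaks <- tibble::tibble(peak_id = 1:2, apex_time = 1:2,
                          left_bound = c(0.5, 1.5),
                          right_bound = c(1.4, 2.4),
                          height = 1, area = 1)
  # {1, 2} features per peak -> 1.5, stays 1.5; {1,1,2,...}: craft 19.05
  links <- tibble::tibble(
    feature_id = 1:3, peak_id = c(1L, 2L, 2L),
    similarity = 0.9, status_shape = "major"
  )
  st <- summarize_links(links, ann_row(1L, 0.9, 0.9)[0, ], peaks, "none")
  expect_equal(st$mean_features_per_peak, 1.5)
})

test_that("the report lists retained candidates per peak and keeps unannotated peaks", {
  sc <- reporting_scenario()
  rep <- build_report(sc$peaks, sc$cas, sc$ann)
  expect_identical(nrow(rep), 3L)
  expect_equal(rep$area_fraction, c(20, 30, 50) / 100)
  expect_equal(sum(rep$area_fraction), 1)

  r1 <- rep[rep$peak_id == 1L, ]
  expect_identical(sort(r1$candidates[[1]]$structure_id), c("S-A", "S-B"))
  r3 <- rep[rep$peak_id == 3L, ]
  expect_identical(nrow(r3$candidates[[1]]), 0L)
  expect_identical(r3$flags, "no_confident_annotation")

  empty <- build_report(sc$peaks[0, ],
                        apply_filter_cascade(sc$links[0, ], sc$ann[0, ]),
                        sc$ann[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("pseudochromatogram bars carry peak areas bit-exactly with annotation categories", {
  sc <- reporting_scenario()
  rep <- build_report(sc$peaks, sc$cas, sc$ann)
  bars <- pseudochromatogram(rep, "taxon-level")
  expect_identical(bars$value, rep$area) # no re-integration
  expect_identical(bars$category[1], "species")
  expect_identical(bars$category[3], "none")

  expect_identical(nrow(pseudochromatogram(rep[0, ], "npc-pathway")), 0L)
  expect_error(pseudochromatogram(rep, "nonsense"))
})

test_that("treemap fractions mirror hand-computed area shares and sum to one", {
  sc <- reporting_scenario()
  rep <- build_report(sc$peaks, sc$cas, sc$ann)
  tm <- treemap_fractions(rep, sc$cas, sc$ann, "cad_area")
  # annotated majors: peak 1 (Terpenoids, 20), peak 2 (Polyketides, 30)
  expect_equal(sum(tm$fraction), 1, tolerance = 1e-9)
  expect_equal(tm$fraction[tm$category == "Polyketides"], 30 / 50)
  expect_equal(tm$fraction[tm$category == "Terpenoids"], 20 / 50)

  tm_minor <- treemap_fractions(rep, sc$cas, sc$ann, "count")
  expect_equal(sum(tm_minor$fraction), 1, tolerance = 1e-9)

  empty <- treemap_fractions(rep[0, ], sc$cas, sc$ann[0, ], "cad_area")
  expect_identical(nrow(empty), 0L)
})

test_that("alluvial bins partition the peaks at every stage", {
  sc <- reporting_scenario()
  al <- alluvial_counts(sc$cas, sc$peaks)
  totals <- al |>
    dplyr::group_by(stage) |>
    dplyr::summarise(n = sum(n_peaks))
  expect_true(all(totals$n == nrow(sc$peaks)))
  # final stage by hand: peak1 two structures, peak2 one, peak3 zero
  fin <- al[al$stage == "shape+taxon+confidence", ]
  expect_identical(fin$n_peaks[fin$bin == "0"], 1L)
  expect_identical(fin$n_peaks[fin$bin == "1"], 1L)
  expect_identical(fin$n_peaks[fin$bin == "2"], 1L)
})

test_that("network decoration maps areas onto nodes and survives a GraphML round-trip", {
  sc <- reporting_scenario()
  g <- network_from_tables(
    tibble::tibble(feature_id = 1:9),
    tibble::tibble(from = c(1L, 3L), to = c(2L, 4L))
  )
  dg <- decorate_network(g, sc$peaks, sc$cas, sc$ann)
  v <- igraph::as_data_frame(dg, "vertices")
  expect_equal(v$cad_area[v$name == "1"], 20) # final major under peak 1
  expect_identical(v$status_final[v$name == "8"], "minor")
  expect_equal(v$cad_area[v$name == "8"], 0)
  expect_identical(v$npc_pathway[v$name == "4"], "unannotated")

  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(dg, path)
  back <- igraph::as_data_frame(read_network(path), "vertices")
  expect_equal(back$cad_area[match(v$name, back$name)], v$cad_area)
  expect_identical(back$status_final[match(v$name, back$name)],
                   v$status_final)
})
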