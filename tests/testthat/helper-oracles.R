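# Analytic/brute-force helpers kept independent of the package internals
# they are used to check.

gauss <- function(t, mu, sigma, h = 1) h * exp(-0.5 * ((t - mu) / sigma)^2)

# uniform trace holding a sum of Gaussians (+ optional noise), rate in Hz
gauss_trace <- function(mus, sigmas, hs, span, rate = 60, noise_sd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(span[1], span[2], by = 1 / (60 * rate))
  y <- rep(0, length(t))
  for (i in seq_along(mus)) y <- y + gauss(t, mus[i], sigmas[i], hs[i])
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  tibble::tibble(time = t, intensity = y)
}

# numeric FWHM by linear interpolation of the half-maximum crossings
fwhm_numeric <- function(trace) {
  y <- trace$intensity
  t <- trace$time
  apex <- which.max(y)
  half <- y[apex] / 2
  li <- max(which(y[1:apex] <= half))
  ri <- apex - 1 + min(which(y[apex:length(y)] <= half))
  tl <- t[li] + (half - y[li]) / (y[li + 1] - y[li]) * (t[li + 1] - t[li])
  tr <- t[ri - 1] + (half - y[ri - 1]) / (y[ri] - y[ri - 1]) * (t[ri] - t[ri - 1])
  tr - tl
}

trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# straight-line re-implementation of the filter cascade: explicit loops,
# no dplyr, no shared code with apply_filter_cascade()
brute_cascade <- function(links, annotations, species = 0.9, genus = 0.8,
                          min_conf = 0.4, tol = 1e-9) {
  n <- nrow(links)
  best_tax <- rep(NA_real_, n)
  best_conf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- which(annotations$feature_id == links$feature_id[i])
    if (length(rows) > 0) {
      b <- rows[which.min(annotations$rank[rows])]
      best_tax[i] <- annotations$taxonomic_distance_score[b]
      best_conf[i] <- annotations$final_score[b]
    }
  }
  keep_tax <- rep(FALSE, n)
  for (pid in unique(links$peak_id[!is.na(links$peak_id)])) {
    idx <- which(!is.na(links$peak_id) & links$peak_id == pid &
                   links$status_shape == "major")
    if (length(idx) == 0) next
    sc <- best_tax[idx]
    is_sp <- !is.na(sc) & abs(sc - species) <= tol
    is_gn <- !is.na(sc) & abs(sc - genus) <= tol
    if (any(is_sp)) {
      keep_tax[idx[is_sp]] <- TRUE
    } else if (any(is_gn)) {
      keep_tax[idx[is_gn]] <- TRUE
    } else {
      keep_tax[idx] <- TRUE
    }
  }
  final <- rep("minor", n)
  for (i in seq_len(n)) {
    if (keep_tax[i] && !is.na(best_conf[i]) && best_conf[i] > min_conf) {
      final[i] <- "major"
    }
  }
  final
}

# random pure-table fixture for cascade tests
random_cascade_fixture <- function(seed) {
  set.seed(seed)
  n_feat <- sample(10:40, 1)
  n_peak <- sample(2:6, 1)
  peak_id <- sample(c(seq_len(n_peak), NA), n_feat, replace = TRUE)
  sim <- ifelse(is.na(peak_id), NA_real_, runif(n_feat))
  links <- tibble::tibble(
    feature_id = seq_len(n_feat),
    peak_id = as.integer(peak_id),
    similarity = sim,
    status_shape = ifelse(!is.na(sim) & sim >= 0.8, "major", "minor")
  )
  ann_feats <- sample(n_feat, size = round(0.8 * n_feat))
  ann <- purrr::map(ann_feats, function(f) {
    k <- sample(1:3, 1)
    tibble::tibble(
      feature_id = f, rank = seq_len(k),
      structure_id = sprintf("S%d-%d", f, seq_len(k)),
      molecular_formula = sprintf("C%dH%d", f, seq_len(k)),
      npc_pathway = sample(c("Terpenoids", "Alkaloids", "Polyketides"), k,
                           replace = TRUE),
      npc_superclass = "X", npc_class = "Y",
      taxonomic_distance_score = sample(c(0.9, 0.8, 0.6, 0.3), k,
                                        replace = TRUE),
      final_score = round(runif(k, 0, 1.2), 3),
      closest_organism = "Z", taxon_level = "species"
    )
  }) |>
    purrr::list_rbind()
  list(links = links, annotations = ann)
}

# tiny annotation table builder
ann_row <- function(feature_id, tax, conf, rank = 1L,
                    structure = sprintf("S%d", feature_id),
                    mf = "C10H12O2", pathway = "Terpenoids") {
  tibble::tibble(
    feature_id = feature_id, rank = rank, structure_id = structure,
    molecular_formula = mf, npc_pathway = pathway,
    npc_superclass = "Triterpenoids", npc_class = "Oleanane triterpenoids",
    taxonomic_distance_score = tax, final_score = conf,
    closest_organism = "Species alpha", taxon_level = "species"
  )
}
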