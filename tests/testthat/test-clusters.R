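# Kernel density, FDR calibration against the uniform-placement null,
# run extraction with merge/length rules, and control filtering.

make_density <- function(values, n_source = sum(values), bandwidth = 25,
                         circular = TRUE) {
  structure(list(values = values, bandwidth = bandwidth, n_source = n_source,
                 genome_length = length(values), circular = circular,
                 normalization = "raw"),
            class = "density_track")
}

make_centers <- function(counts, circular = TRUE) {
  structure(list(counts = counts, genome_length = length(counts),
                 circular = circular, shift_used = 25,
                 n_centers = sum(counts), n_dropped = 0L),
            class = "center_set")
}

test_that("KDE matches the Gaussian closed form and conserves mass", {
  G <- 10000
  counts <- numeric(G); counts[501] <- 1 # single center at 500
  dens <- kde_density(make_centers(counts), bandwidth = 25)
  expect_equal(dens$values[501], 1 / (25 * sqrt(2 * pi)), tolerance = 1e-9)
  expect_equal(dens$values[526], dens$values[501] * exp(-1 / 2), tolerance = 1e-9)
  expect_equal(dens$values[476], dens$values[501] * exp(-1 / 2), tolerance = 1e-9)
  set.seed(8)
  counts2 <- tabulate(sample.int(G, 500, TRUE), G)
  dens2 <- kde_density(make_centers(counts2), bandwidth = 25)
  expect_lt(abs(sum(dens2$values) - 500), 1e-6)
})

test_that("KDE agrees with a naive double loop", {
  G <- 10000
  set.seed(17)
  pos <- sample.int(G, 200, TRUE) - 1
  dens <- kde_density(make_centers(tabulate(pos + 1, G)), bandwidth = 25)
  expect_equal(dens$values, naive_kde(pos, G, 25), tolerance = 1e-10)
})

test_that("cluster extraction applies the merge and length rules", {
  G <- 1000
  v <- numeric(G)
  v[101:140] <- 1 # run [100, 140)
  v[151:200] <- 1 # run [150, 200), gap 10 < 25 -> merged
  v[501:520] <- 1 # run [500, 520), length 20 < 25 -> discarded
  cl <- call_clusters(make_density(v), threshold = 0.5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 100)
  expect_equal(cl$end, 200)
  expect_true(cl$summit >= cl$start && cl$summit < cl$end)
})

test_that("clusters merge across the origin of a circular genome", {
  G <- 1000
  v <- numeric(G)
  v[981:1000] <- 1 # [980, 1000)
  v[1:20] <- 1     # [0, 20), wrap gap 0
  cl <- call_clusters(make_density(v), threshold = 0.5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$end - cl$start, 40)
  expect_equal(cl$start, 980)
  # on a linear genome the two stay separate but are then too short
  cl_lin <- call_clusters(make_density(v, circular = FALSE), threshold = 0.5)
  expect_equal(nrow(cl_lin), 0)
})

test_that("called clusters respect minimum gap and length on random tracks", {
  set.seed(23)
  for (rep in 1:5) {
    v <- abs(smooth_running_window(rnorm(5000), 51))
    thr <- stats::quantile(v, stats::runif(1, 0.7, 0.95))
    cl <- call_clusters(make_density(v), thr, min_length = 25, merge_gap = 25)
    if (nrow(cl) > 1) {
      gaps <- cl$start[-1] - cl$end[-nrow(cl)]
      expect_true(all(gaps >= 25))
    }
    if (nrow(cl) > 0) expect_true(all(cl$end - cl$start >= 25))
  }
})

test_that("FDR calibration is deterministic and monotone in the target", {
  set.seed(41)
  G <- 50000
  counts <- tabulate(sample.int(G, 5000, TRUE), G)
  counts[1001:1200] <- counts[1001:1200] + 5 # a dense region
  dens <- kde_density(make_centers(counts), bandwidth = 25)
  cal1 <- calibrate_fdr_threshold(dens, fdr = 1e-3, n_rand = 10, seed = 3)
  cal2 <- calibrate_fdr_threshold(dens, fdr = 1e-3, n_rand = 10, seed = 3)
  expect_identical(cal1$density_threshold, cal2$density_threshold)
  loose <- calibrate_fdr_threshold(dens, fdr = 0.5, n_rand = 10, seed = 3)
  expect_lte(loose$density_threshold, cal1$density_threshold)
})

test_that("on null data the called fraction respects the FDR target", {
  set.seed(19)
  G <- 200000
  counts <- tabulate(sample.int(G, 40000, TRUE), G) # uniform: observed = null model
  dens <- kde_density(make_centers(counts), bandwidth = 25)
  cal <- calibrate_fdr_threshold(dens, fdr = 1e-3, n_rand = 20, seed = 5)
  cl <- call_clusters(dens, cal$density_threshold)
  called_bp <- if (nrow(cl)) sum(cl$end - cl$start) else 0
  expect_lte(called_bp / G, 5e-3)
})

test_that("doubling all counts and recalibrating leaves calls stable", {
  cfg <- small_config()
  gen <- generate_genome(cfg)
  tags <- generate_nucleoid_tags(gen$sequence, gen$truth, cfg)
  centers <- to_fragment_centers(tags, cfg$footprint_length)
  dens <- kde_density(centers)
  cal <- calibrate_fdr_threshold(dens, n_rand = 10, seed = 2)
  cl <- call_clusters(dens, cal$density_threshold)
  doubled <- make_centers(centers$counts * 2)
  dens2 <- kde_density(doubled)
  cal2 <- calibrate_fdr_threshold(dens2, n_rand = 10, seed = 2)
  cl2 <- call_clusters(dens2, cal2$density_threshold)
  # interval sets should largely coincide (Jaccard on covered bp)
  cov1 <- logical(cfg$genome_length); cov2 <- logical(cfg$genome_length)
  for (i in seq_len(nrow(cl))) cov1[(cl$start[i]:(cl$end[i] - 1)) %% cfg$genome_length + 1] <- TRUE
  for (i in seq_len(nrow(cl2))) cov2[(cl2$start[i]:(cl2$end[i] - 1)) %% cfg$genome_length + 1] <- TRUE
  jaccard <- sum(cov1 & cov2) / sum(cov1 | cov2)
  expect_gt(jaccard, 0.8)
})

test_that("control filtering keeps finite ratios and honors the boundary", {
  G <- 10000
  v <- numeric(G); v[2001:2100] <- 1
  nuc <- make_density(v, n_source = 100)
  cl <- call_clusters(nuc, 0.5)
  # zero control everywhere: ratios finite, everything retained
  ctl0 <- make_density(numeric(G), n_source = 100)
  out0 <- filter_by_control(cl, nuc, ctl0, min_ratio = 1)
  expect_equal(nrow(out0), nrow(cl))
  expect_true(all(is.finite(out0$enrichment_ratio)))
  # identical tracks: ratio exactly 1, retained at min_ratio 1, removed above
  out1 <- filter_by_control(cl, nuc, nuc, min_ratio = 1)
  expect_equal(out1$enrichment_ratio, rep(1, nrow(cl)))
  expect_equal(nrow(out1), nrow(cl))
  out2 <- filter_by_control(cl, nuc, nuc, min_ratio = 1.5)
  expect_equal(nrow(out2), 0)
})

test_that("recovered cluster lengths sit in the planted-span envelope", {
  cl <- default_clusters()$filtered
  cfg <- default_config()
  med <- stats::median(cl$end - cl$start)
  max_span <- (cfg$footprints_per_cluster[2] - 1) * cfg$footprint_spacing_period +
    cfg$footprint_length
  expect_gte(med, cfg$footprint_length)
  expect_lte(med, max_span + 2 * 25) # allow KDE bleed of about one bandwidth per side
})
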