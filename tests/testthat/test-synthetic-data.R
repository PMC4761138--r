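# The synthetic-data generator: configuration validation, determinism,
# planted-structure self-consistency, and the statistical properties the
# downstream analyses rely on.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(genome_length = -1), "genome_length")
  expect_error(sim_config(gc_content = 1.3), "gc_content")
  expect_error(sim_config(footprint_length = 100, footprint_spacing_period = 93),
               "footprint_length")
  expect_error(sim_config(tag_length = 60), "tag_length")
  expect_error(sim_config(paired_end_prob = -0.1), "paired_end_prob")
  expect_error(sim_config(footprints_per_cluster = c(5, 2)), "footprints_per_cluster")
})

test_that("every generator is deterministic given the seed", {
  cfg <- small_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth, g2$truth)
  n1 <- generate_nucleoid_tags(g1$sequence, g1$truth, cfg)
  n2 <- generate_nucleoid_tags(g2$sequence, g2$truth, cfg)
  expect_identical(n1$counts_plus, n2$counts_plus)
  expect_identical(n1$counts_minus, n2$counts_minus)
  c1 <- generate_control_tags(g1$sequence, cfg)
  c2 <- generate_control_tags(g1$sequence, cfg)
  expect_identical(c1$counts_plus, c2$counts_plus)
  # a different seed changes the output
  g3 <- generate_genome(small_config(seed = 8))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("without planting, base composition matches the configured GC content", {
  cfg <- small_config(atract_cluster_rate = 0, n_genes = 0)
  gen <- generate_genome(cfg)
  expect_identical(nrow(gen$truth$planted_atracts), 0L)
  gc <- gc_content(gen$sequence)
  se <- sqrt(cfg$gc_content * (1 - cfg$gc_content) / cfg$genome_length)
  expect_lt(abs(gc - cfg$gc_content), 4 * se)
})

test_that("planted A-tracts are pure A/T, length-bounded, and found by the scanner", {
  sim <- default_sim()
  planted <- sim$truth$planted_atracts
  expect_gt(nrow(planted), 100)
  expect_true(all(planted$nA >= 0 & planted$nT >= 0))
  expect_true(all(planted$length >= 3 & planted$length <= 10))
  seqv <- strsplit(sim$sequence, "")[[1]]
  for (i in sample(nrow(planted), 50)) {
    bases <- seqv[(planted$start[i] + 1):planted$end[i]]
    expect_identical(bases, c(rep("A", planted$nA[i]), rep("T", planted$nT[i])))
  }
  found <- find_atracts(sim$sequence)
  key <- paste(found$start, found$end, found$nA, found$nT)
  expect_true(all(paste(planted$start, planted$end, planted$nA, planted$nT) %in% key))
})

test_that("ground-truth footprints are ordered, non-overlapping and periodic", {
  truth <- default_sim()$truth
  fp <- truth$footprints
  expect_true(all(diff(fp$start) > 0))
  expect_true(all(fp$start >= 0 & fp$end <= default_config()$genome_length))
  same_cluster <- fp$cluster[-1] == fp$cluster[-nrow(fp)]
  ctr <- (fp$start + fp$end) / 2
  spacing <- diff(ctr)[same_cluster]
  expect_true(all(spacing == default_config()$footprint_spacing_period))
  expect_true(all(fp$start[-1][same_cluster] >= fp$end[-nrow(fp)][same_cluster]))
})

test_that("paired tags with no jitter sit exactly one footprint apart", {
  cfg <- small_config(paired_end_prob = 1, boundary_jitter_sd = 0,
                      tss_depletion_depth = 0)
  gen <- generate_genome(cfg)
  tags <- generate_nucleoid_tags(gen$sequence, gen$truth, cfg)
  # every plus tag at p has its partner minus tag at p + footprint_length - 1
  shifted <- c(tail(tags$counts_plus, cfg$footprint_length - 1),
               head(tags$counts_plus, -(cfg$footprint_length - 1)))
  # the final fragment of the stream may have had its minus tag trimmed
  expect_lte(sum(abs(tags$counts_minus - shifted)), 1)
})

test_that("complete TSS/TES depletion leaves no fragment centers in the window", {
  cfg <- small_config(tss_depletion_depth = 1)
  gen <- generate_genome(cfg)
  tags <- generate_nucleoid_tags(gen$sequence, gen$truth, cfg)
  frags <- attr(tags, "fragments")
  centers <- (frags$left + frags$right) %/% 2
  sites <- c(gen$truth$genes$tss, gen$truth$genes$tes)
  dmin <- vapply(centers, function(p)
    min(nucfoot:::circ_dist(p, sites, cfg$genome_length)), numeric(1))
  expect_true(all(dmin > cfg$tss_depletion_halfwidth))
})

test_that("sampled fragment lengths average the footprint length", {
  frags <- attr(default_sim()$nucleoid, "fragments")
  mean_len <- mean(frags$right - frags$left + 1)
  expect_lt(abs(mean_len - default_config()$footprint_length), 1)
})

test_that("unbiased control tags are uniform (chi-square goodness of fit)", {
  cfg <- small_config(at_bias = 1)
  gen <- generate_genome(cfg)
  tags <- generate_control_tags(gen$sequence, cfg)
  # bin plus-strand 5'-end counts into 1-kb bins and test against uniform
  bins <- tapply(tags$counts_plus, rep(1:100, each = 1000), sum)
  p <- stats::chisq.test(bins)$p.value
  expect_gt(p, 0.01)
})

test_that("tag totals are exactly as configured", {
  sim <- default_sim()
  cfg <- default_config()
  # injected spikes add on top of the configured totals
  expect_gte(sim$nucleoid$n_tags, cfg$n_nucleoid_tags)
  clean <- generate_nucleoid_tags(sim$sequence, sim$truth, cfg)
  expect_identical(clean$n_tags, as.numeric(cfg$n_nucleoid_tags))
  clean_ctl <- generate_control_tags(sim$sequence, cfg)
  expect_identical(clean_ctl$n_tags, as.numeric(cfg$n_control_tags))
})

test_that("anomaly injection spikes the expected number of positions", {
  cfg <- small_config(anomaly_spike_rate = 1e-4) # ~10 per strand on 100 kb
  gen <- generate_genome(cfg)
  tags <- generate_nucleoid_tags(gen$sequence, gen$truth, cfg)
  spiked <- inject_anomalies(tags, cfg)
  inj <- attr(spiked, "injected")
  per_strand <- table(factor(inj$strand, c("+", "-")))
  expect_true(all(per_strand >= 1 & per_strand <= 30)) # Poisson(10) envelope
  for (s in c("+", "-")) {
    v <- if (s == "+") tags$counts_plus else tags$counts_minus
    m <- mean(v[v >= 1])
    vs <- if (s == "+") spiked$counts_plus else spiked$counts_minus
    expect_true(all(vs[inj$position[inj$strand == s] + 1] >= 50 * m))
  }
  # rate zero is the identity
  cfg0 <- small_config(anomaly_spike_rate = 0)
  same <- inject_anomalies(tags, cfg0)
  expect_identical(same$counts_plus, tags$counts_plus)
  expect_identical(same$counts_minus, tags$counts_minus)
})

test_that("nucleoid sampling requires footprints", {
  cfg <- small_config(cluster_rate = 0)
  gen <- generate_genome(cfg)
  expect_identical(nrow(gen$truth$footprints), 0L)
  expect_error(generate_nucleoid_tags(gen$sequence, gen$truth, cfg), "footprints")
})
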