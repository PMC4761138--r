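# Fragment centers and strand-oriented metagene profiles.

test_that("center shifting follows the half-fragment-size convention", {
  G <- 1000
  cp <- numeric(G); cp[101] <- 1  # plus tag at 100
  cm <- numeric(G); cm[150] <- 1  # minus tag at 149
  tags <- tag_set(cp, cm, G)
  centers <- to_fragment_centers(tags, 50)
  expect_equal(which(centers$counts > 0) - 1, c(124, 125)) # 149-25 and 100+25
  expect_equal(centers$shift_used, 25)
  expect_equal(centers$n_centers, 2) # conservation
})

test_that("paired tags from one fragment give nearly coincident centers", {
  cfg <- small_config(paired_end_prob = 1, boundary_jitter_sd = 0,
                      tss_depletion_depth = 0)
  gen <- generate_genome(cfg)
  tags <- generate_nucleoid_tags(gen$sequence, gen$truth, cfg)
  centers <- to_fragment_centers(tags, cfg$footprint_length)
  expect_equal(centers$n_centers, tags$n_tags)
  # a 50-bp fragment puts the plus center at L+25 and the minus center at L+24
  frags <- attr(tags, "fragments")
  plus_centers <- frags$left + 25
  minus_centers <- frags$right[frags$paired] - 25
  expect_true(all(abs(sort(plus_centers[frags$paired]) - sort(minus_centers)) <= 1))
})

test_that("center totals are conserved on a circular genome", {
  tags <- random_tag_set(G = 4000, n = 600, seed = 2)
  centers <- to_fragment_centers(tags, 50)
  expect_equal(sum(centers$counts), tags$n_tags)
})

test_that("metagene bookkeeping places centers at the right offsets", {
  G <- 5000
  counts <- numeric(G); counts[951] <- 1; counts[1051] <- 1 # centers at 950, 1050
  cs <- structure(list(counts = counts, genome_length = G, circular = TRUE,
                       shift_used = 25, n_centers = 2, n_dropped = 0L),
                  class = "center_set")
  plus_gene <- data.frame(name = "g", tss = 1000, tes = 1999, strand = "+",
                          start = 1000, end = 2000)
  mp <- metagene_profile(cs, plus_gene, "tss", flank = 100, window = 1)
  expect_equal(mp$offsets[mp$mean_value > 0], c(-50, 50))
  # a minus-strand gene with the same TSS sees the mirror image
  minus_gene <- data.frame(name = "g", tss = 1000, tes = 1, strand = "-",
                           start = 1, end = 1001)
  mm <- metagene_profile(cs, minus_gene, "tss", flank = 100, window = 1)
  expect_equal(mm$offsets[mm$mean_value > 0], c(-50, 50))
  expect_equal(mm$mean_value, rev(mp$mean_value))
})

test_that("metagene of uniform random centers is flat", {
  G <- 200000
  set.seed(31)
  counts <- tabulate(sample.int(G, 100000, TRUE), G)
  cs <- structure(list(counts = counts, genome_length = G, circular = TRUE,
                       shift_used = 25, n_centers = sum(counts), n_dropped = 0L),
                  class = "center_set")
  n_genes <- 200
  genes <- data.frame(name = paste0("g", 1:n_genes),
                      tss = sample.int(G, n_genes) - 1,
                      strand = sample(c("+", "-"), n_genes, TRUE))
  genes$tes <- (genes$tss + ifelse(genes$strand == "+", 999, -999)) %% G
  mp <- metagene_profile(cs, genes, "tss", flank = 500, window = 1)
  lambda <- sum(counts) / G
  se <- sqrt(lambda / n_genes)
  z <- (mp$mean_value - lambda) / se
  expect_lt(mean(abs(z) > 3), 0.01) # ~binomial tail at 3 SE
  expect_lt(max(abs(z)), 5)
})

test_that("reversing the genome and strands leaves the metagene unchanged", {
  G <- 10000
  set.seed(13)
  counts <- tabulate(sample.int(G, 3000, TRUE), G)
  cs <- structure(list(counts = counts, genome_length = G, circular = TRUE,
                       shift_used = 25, n_centers = sum(counts), n_dropped = 0L),
                  class = "center_set")
  genes <- data.frame(name = c("a", "b"), tss = c(2000, 7000), tes = c(2999, 6001),
                      strand = c("+", "-"), start = c(2000, 6001), end = c(3000, 7001))
  mp <- metagene_profile(cs, genes, "tss", flank = 300, window = 1)
  # mirror: position p -> G - 1 - p, strands flipped
  cs_rev <- cs; cs_rev$counts <- rev(counts)
  genes_rev <- genes
  genes_rev$tss <- G - 1 - genes$tss
  genes_rev$tes <- G - 1 - genes$tes
  genes_rev$strand <- ifelse(genes$strand == "+", "-", "+")
  mp_rev <- metagene_profile(cs_rev, genes_rev, "tss", flank = 300, window = 1)
  expect_equal(mp_rev$mean_value, mp$mean_value)
})

test_that("GC metaprofile identities hold", {
  allgc <- paste(rep("G", 3000), collapse = "")
  gene <- data.frame(name = "g", tss = 1500, tes = 2000, strand = "+",
                     start = 1500, end = 2001)
  gp <- gc_metaprofile(allgc, gene, "tss", flank = 200, window = 1)
  expect_true(all(gp$mean_value == 1))
  # single gene: the profile is the gene's own 0/1 GC indicator
  set.seed(5)
  seqv <- sample(c("A", "C", "G", "T"), 3000, TRUE)
  gp2 <- gc_metaprofile(paste(seqv, collapse = ""), gene, "tss",
                        flank = 200, window = 1)
  expect_equal(gp2$mean_value, as.numeric(seqv[(1500 - 200):(1500 + 200) + 1] %in% c("G", "C")))
})

test_that("A-tract metaprofile marks covered offsets", {
  gene <- data.frame(name = "g", tss = 1000, tes = 1800, strand = "+",
                     start = 1000, end = 1801)
  none <- find_atracts(paste(rep("C", 3000), collapse = ""))
  ap0 <- atract_metaprofile(none, gene, 3000, flank = 100)
  expect_true(all(ap0$mean_value == 0))
  # one tract covering offsets +10..+15
  tracts <- data.frame(start = 1010, end = 1016, nA = 3, nT = 3, length = 6)
  ap <- atract_metaprofile(tracts, gene, 3000, flank = 100)
  expect_equal(ap$offsets[ap$mean_value == 1], 10:15)
})

test_that("the planted TSS accessibility dip is recovered with its width", {
  centers <- default_centers()
  truth <- default_sim()$truth
  cfg <- default_config()
  mp <- metagene_profile(centers, truth$genes, "tss", flank = 500, window = 50)
  s <- mp$smoothed
  baseline <- mean(s[abs(mp$offsets) > 200])
  depth <- baseline - min(s)
  expect_gt(depth / baseline, 0.3) # a clear dip
  # minimum inside the planted depletion window
  expect_lte(abs(mp$offsets[which.min(s)]), cfg$tss_depletion_halfwidth)
  # width at half depth within 25% of the planted 2 x halfwidth
  below <- mp$offsets[s < baseline - depth / 2]
  width <- diff(range(below))
  expect_lt(abs(width - 2 * cfg$tss_depletion_halfwidth),
            0.25 * 2 * cfg$tss_depletion_halfwidth)
  # the TES shows a dip as well
  mp2 <- metagene_profile(centers, truth$genes, "tes", flank = 500, window = 50)
  base2 <- mean(mp2$smoothed[abs(mp2$offsets) > 200])
  expect_gt((base2 - min(mp2$smoothed)) / base2, 0.3)
})

test_that("promoter sequence composition shows reduced GC and planted tracts", {
  sim <- default_sim()
  genes <- sim$truth$genes
  gp <- gc_metaprofile(sim$sequence, genes, "tss")
  prom <- gp$smoothed[gp$offsets >= -100 & gp$offsets <= 20]
  distal <- gp$smoothed[abs(gp$offsets) > 300]
  expect_lt(mean(prom), mean(distal) - 0.01)
  tracts <- find_atracts(sim$sequence)
  ap <- atract_metaprofile(tracts, genes, nchar(sim$sequence))
  peak_offset <- ap$offsets[which.max(ap$smoothed)]
  expect_gte(peak_offset, -100)
  expect_lte(peak_offset, 20)
})
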