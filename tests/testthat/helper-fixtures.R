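# Shared fixtures and independent oracles. The default simulation (the
# documented study preset: 1-Mb circular genome, ~200k nucleoid tags) is
# expensive, so it is built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_config <- function() sim_config(seed = 1)

default_sim <- function() memo("sim", function() simulate_dataset(default_config()))

default_nucleoid_qc <- function() memo("nuc_qc", function() {
  filter_anomalous_positions(default_sim()$nucleoid)
})

default_control_qc <- function() memo("ctl_qc", function() {
  filter_anomalous_positions(default_sim()$control)
})

default_fragment_estimate <- function() memo("frag_est", function() {
  estimate_fragment_size(strand_cross_correlation(default_nucleoid_qc()$tags))
})

default_centers <- function() memo("centers", function() {
  to_fragment_centers(default_nucleoid_qc()$tags,
                      default_fragment_estimate()$fragment_size)
})

default_density <- function() memo("density", function() kde_density(default_centers()))

default_clusters <- function() memo("clusters", function() {
  dens <- default_density()
  cal <- calibrate_fdr_threshold(dens, fdr = 1e-3, n_rand = 20, seed = 20)
  cl <- call_clusters(dens, cal$density_threshold)
  ctl <- to_fragment_centers(default_control_qc()$tags,
                             default_fragment_estimate()$fragment_size)
  list(calibration = cal,
       unfiltered = cl,
       filtered = filter_by_control(cl, dens, kde_density(ctl)))
})

# A small, fast simulation for structural tests that do not need the full
# preset statistics.
small_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 100000, n_genes = 50, n_nucleoid_tags = 20000,
         n_control_tags = 20000, seed = 7),
    list(...))
  do.call(sim_config, args)
}

# ---- independent oracles ---------------------------------------------------

# Character-by-character A-tract scanner, deliberately naive.
naive_atracts <- function(seqv, min_len = 3, max_len = 10) {
  n <- length(seqv)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (seqv[i] == "A" || seqv[i] == "T") {
      start <- i
      nA <- 0L
      while (i <= n && seqv[i] == "A") { nA <- nA + 1L; i <- i + 1L }
      nT <- 0L
      while (i <= n && seqv[i] == "T") { nT <- nT + 1L; i <- i + 1L }
      len <- nA + nT
      if (len >= min_len && len <= max_len)
        out[[length(out) + 1L]] <- c(start - 1L, start - 1L + len, nA, nT, len)
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0), nA = integer(0),
                      nT = integer(0), length = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "nA", "nT", "length")
  df
}

# O(n * k) circular Pearson autocorrelation via stats::cor on rotations.
naive_circular_cor <- function(x, y, lags) {
  n <- length(y)
  vapply(lags, function(d) {
    yd <- c(y[(d + 1):n], y[seq_len(d)])
    if (d == 0) yd <- y
    stats::cor(x, yd)
  }, numeric(1))
}

# Double-loop Gaussian KDE on a circle.
naive_kde <- function(center_positions, G, bw) {
  v <- numeric(G)
  for (p in center_positions) {
    d <- abs(0:(G - 1) - p)
    d <- pmin(d, G - d)
    v <- v + stats::dnorm(d, sd = bw)
  }
  v
}

# Explained sum of squares of a least-squares sinusoid fit at Fourier
# frequency k of an n-point series.
ls_sinusoid_ess <- function(y, k) {
  n <- length(y)
  t <- seq_len(n) - 1
  X <- cbind(cos(2 * pi * k * t / n), sin(2 * pi * k * t / n))
  fit <- stats::lm.fit(cbind(1, X), y)
  sum((y - mean(y))^2) - sum(fit$residuals^2)
}

# Reciprocal-overlap cluster recovery fraction.
recovered_fraction <- function(truth_df, called_df, min_overlap = 0.5) {
  if (nrow(truth_df) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth_df)), function(i) {
    ov <- pmin(truth_df$end[i], called_df$end) - pmax(truth_df$start[i], called_df$start)
    any(ov > 0 &
          ov >= min_overlap * (truth_df$end[i] - truth_df$start[i]) &
          ov >= min_overlap * (called_df$end - called_df$start))
  }, logical(1))
  mean(hit)
}

random_tag_set <- function(G = 2000, n = 500, seed = 1, tag_length = 36) {
  set.seed(seed)
  tag_set(tabulate(sample.int(G, n, TRUE), G), tabulate(sample.int(G, n, TRUE), G),
          G, circular = TRUE, tag_length = tag_length)
}
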