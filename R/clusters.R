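# Cluster calling: Gaussian kernel density of fragment centers, empirical
# FDR calibration against uniform-placement randomizations, run extraction
# with merging/length rules, and control-enrichment filtering.

#' Gaussian kernel density of fragment centers
#'
#' Evaluates, at every genome position, the sum of Gaussian contributions of
#' all fragment centers (bandwidth = standard deviation). On a circular
#' genome the kernel wraps and the density is computed exactly by circular
#' FFT convolution with the full wrapped kernel, so total density mass
#' equals the number of centers; on a linear genome the track is computed by
#' zero-padded convolution.
#'
#' @param centers a `center_set` from [to_fragment_centers()].
#' @param bandwidth Gaussian sigma in bp.
#' @return a `density_track`: `values` (fragments per bp), `bandwidth`,
#'   `n_source`, `normalization` (`"raw"`).
#' @export
kde_density <- function(centers, bandwidth = 25) {
  stopifnot(inherits(centers, "center_set"))
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be positive", call. = FALSE)
  if (centers$n_centers < 1) stop("at least one center is required", call. = FALSE)
  values <- kde_convolve(centers$counts, bandwidth, centers$circular)
  structure(list(values = values, bandwidth = bandwidth,
                 n_source = centers$n_centers, genome_length = centers$genome_length,
                 circular = centers$circular, normalization = "raw"),
            class = "density_track")
}

kde_convolve <- function(counts, bandwidth, circular, kernel_fft = NULL) {
  G <- length(counts)
  if (circular) {
    if (is.null(kernel_fft)) kernel_fft <- kde_kernel_fft(G, bandwidth)
    v <- Re(stats::fft(stats::fft(counts) * kernel_fft, inverse = TRUE)) / G
  } else {
    pad <- as.integer(ceiling(8 * bandwidth))
    n <- G + 2L * pad
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    kern <- stats::dnorm(d, sd = bandwidth)
    x <- c(counts, numeric(2L * pad))
    v <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE))[seq_len(G)] / n
  }
  pmax(v, 0)
}

# FFT of the wrapped Gaussian kernel centered at position 0.
kde_kernel_fft <- function(G, bandwidth) {
  j <- 0:(G - 1L)
  stats::fft(stats::dnorm(pmin(j, G - j), sd = bandwidth))
}

#' Normalize a density track to per-million centers
#' @param track a `density_track`.
#' @return the track rescaled as if it came from one million centers.
#' @export
normalize_per_million <- function(track) {
  stopifnot(inherits(track, "density_track"))
  if (identical(track$normalization, "per-million")) return(track)
  track$values <- track$values * 1e6 / track$n_source
  track$normalization <- "per-million"
  track
}

#' Calibrate the density threshold for a target empirical FDR
#'
#' Places the observed number of centers uniformly at random on the genome
#' `n_rand` times, computes the kernel density of each randomization, and
#' tabulates, on a grid of candidate thresholds, the expected number of
#' null positions exceeding each threshold. The calibrated threshold is the
#' smallest `t` for which the mean null exceedance is at most
#' `fdr` times the observed exceedance - i.e. at most a fraction `fdr` of
#' positions called at `t` are expected under the randomization null.
#'
#' @param observed a `density_track` of the observed (nucleoid) centers.
#' @param fdr target positionwise false discovery rate.
#' @param n_rand number of uniform randomizations.
#' @param seed integer seed for the randomizations.
#' @param n_grid number of candidate thresholds.
#' @return an `fdr_calibration`: `density_threshold`, `fdr_target`,
#'   `n_randomizations`, `seed`, and `null_exceedance_curve` (a data.frame
#'   of threshold, mean null positions above, observed positions above).
#'   When no threshold satisfies the target the threshold is set just above
#'   the observed maximum (an empty call set, not an error).
#' @export
calibrate_fdr_threshold <- function(observed, fdr = 1e-3, n_rand = 20,
                                    seed = 1, n_grid = 2048) {
  stopifnot(inherits(observed, "density_track"))
  if (observed$n_source < 1) stop("at least one center is required", call. = FALSE)
  G <- observed$genome_length
  n <- observed$n_source
  grid <- seq(0, max(observed$values), length.out = n_grid)
  obs_sorted <- sort(observed$values)
  obs_above <- G - findInterval(grid, obs_sorted)

  set.seed(seed)
  kfft <- if (observed$circular) kde_kernel_fft(G, observed$bandwidth) else NULL
  null_above <- numeric(n_grid)
  for (r in seq_len(n_rand)) {
    counts <- tabulate(sample.int(G, n, replace = TRUE), nbins = G)
    v <- sort(kde_convolve(counts, observed$bandwidth, observed$circular, kfft))
    null_above <- null_above + (G - findInterval(grid, v))
  }
  null_mean <- null_above / n_rand

  ok <- null_mean <= fdr * obs_above
  threshold <- if (any(ok)) grid[which(ok)[1L]] else max(observed$values) * (1 + 1e-9)
  structure(list(
    density_threshold = threshold,
    fdr_target = fdr,
    n_randomizations = n_rand,
    seed = seed,
    null_exceedance_curve = data.frame(threshold = grid,
                                       null_positions_above = null_mean,
                                       observed_positions_above = obs_above)
  ), class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf("fdr_calibration: density threshold %.5g at FDR %g (%d randomizations)\n",
              x$density_threshold, x$fdr_target, x$n_randomizations))
  invisible(x)
}

#' Call clusters of enriched fragment density
#'
#' Extracts maximal runs of positions whose density reaches the threshold,
#' merges runs separated by less than `merge_gap` (including across the
#' origin of a circular genome), and discards merged runs shorter than
#' `min_length`.
#'
#' @param density a `density_track`.
#' @param threshold density threshold, e.g. from [calibrate_fdr_threshold()].
#' @param min_length minimum cluster length in bp (applied after merging).
#' @param merge_gap runs closer than this many bp are merged.
#' @return a data.frame of class `nucfoot_clusters` with columns `start`,
#'   `end` (0-based half-open; `end` may exceed the genome length for a
#'   cluster wrapping the origin), `summit`, `mean_density`.
#' @export
call_clusters <- function(density, threshold, min_length = 25, merge_gap = 25) {
  stopifnot(inherits(density, "density_track"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive", call. = FALSE)
  v <- density$values
  G <- length(v)
  above <- v >= threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      summit = integer(0), mean_density = numeric(0))
  class(empty) <- c("nucfoot_clusters", "data.frame")
  if (!any(above)) return(empty)

  if (all(above)) {
    out <- data.frame(start = 0L, end = G,
                      summit = which.max(v) - 1L, mean_density = mean(v))
    class(out) <- c("nucfoot_clusters", "data.frame")
    return(out)
  }

  # On a circular genome, rotate the origin into the longest below-threshold
  # gap; every remaining gap is then interior and merging is purely linear.
  rot <- 0L
  if (density$circular) {
    r0 <- rle(above)
    ends0 <- cumsum(r0$lengths)
    starts0 <- ends0 - r0$lengths # 0-based
    below_start <- starts0[!r0$values]
    below_len <- r0$lengths[!r0$values]
    if (!r0$values[1L] && !r0$values[length(r0$values)] && length(below_len) > 1L) {
      # first and last below-runs wrap into one
      below_len[1L] <- below_len[1L] + below_len[length(below_len)]
      below_start[1L] <- below_start[length(below_start)]
      below_len <- below_len[-length(below_len)]
      below_start <- below_start[-length(below_start)]
    }
    if (max(below_len) < merge_gap) {
      # every gap merges: one cluster spanning all but the longest gap
      g <- which.max(below_len)
      s0 <- (below_start[g] + below_len[g]) %% G
      len <- G - below_len[g]
      idx <- (s0 + 0:(len - 1L)) %% G
      out <- data.frame(start = s0, end = s0 + len,
                        summit = idx[which.max(v[idx + 1L])],
                        mean_density = mean(v[idx + 1L]))
      class(out) <- c("nucfoot_clusters", "data.frame")
      return(out)
    }
    rot <- below_start[which.max(below_len)]
    above <- rotate_vec(above, rot)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by < merge_gap
  if (nrow(runs) > 1) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)]
    grp <- cumsum(c(0L, as.integer(gap >= merge_gap)))
    runs <- data.frame(start = as.integer(tapply(runs$start, grp, min)),
                       end = as.integer(tapply(runs$end, grp, max)))
  }
  runs <- runs[runs$end - runs$start >= min_length, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  # map back to original coordinates
  summit <- integer(nrow(runs))
  meand <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- ((runs$start[i]:(runs$end[i] - 1L)) + rot) %% G
    vals <- v[idx + 1L]
    summit[i] <- idx[which.max(vals)]
    meand[i] <- mean(vals)
  }
  start0 <- (runs$start + rot) %% G
  out <- data.frame(start = start0, end = start0 + (runs$end - runs$start),
                    summit = summit, mean_density = meand)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nucfoot_clusters", "data.frame")
  out
}

#' Filter clusters by enrichment over the control sample
#'
#' Annotates each cluster with the ratio of mean per-million-normalized
#' nucleoid density to mean per-million-normalized control density over the
#' cluster (a pseudo-density of 1/genome_length is added to both sides, so
#' control-free regions stay finite and identical tracks give ratio exactly
#' 1), and removes clusters whose ratio falls below `min_ratio`. The full ratio distribution is attached as
#' attribute `"ratios"`.
#'
#' @param clusters a `nucfoot_clusters` data.frame from [call_clusters()].
#' @param nucleoid_density,control_density `density_track`s (normalized to
#'   per-million internally if raw).
#' @param min_ratio minimum nucleoid/control enrichment ratio.
#' @return the filtered clusters with added columns `enrichment_ratio` and
#'   `passed_control_filter`.
#' @export
filter_by_control <- function(clusters, nucleoid_density, control_density,
                              min_ratio = 1.0) {
  stopifnot(inherits(clusters, "nucfoot_clusters"))
  nuc <- normalize_per_million(nucleoid_density)
  ctl <- normalize_per_million(control_density)
  G <- nuc$genome_length
  eps <- 1 / G
  ratio <- numeric(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    idx <- (clusters$start[i]:(clusters$end[i] - 1L)) %% G + 1L
    ratio[i] <- (mean(nuc$values[idx]) + eps) / (mean(ctl$values[idx]) + eps)
  }
  clusters$enrichment_ratio <- ratio
  clusters$passed_control_filter <- ratio >= min_ratio
  out <- clusters[clusters$passed_control_filter, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nucfoot_clusters", "data.frame")
  attr(out, "ratios") <- ratio
  out
}

#' Write clusters as BED6+3
#'
#' Extra columns are summit, mean density and enrichment ratio; the score is
#' a scaled mean density capped at 1000.
#'
#' @param clusters a `nucfoot_clusters` data.frame.
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path, chrom = "chr") {
  if (nrow(clusters) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(round(1000 * clusters$mean_density / max(clusters$mean_density)), 1000)
  er <- if ("enrichment_ratio" %in% names(clusters)) clusters$enrichment_ratio else NA
  lines <- sprintf("%s\t%d\t%d\tcl%d\t%d\t.\t%d\t%.6g\t%.6g",
                   chrom, clusters$start, clusters$end, seq_len(nrow(clusters)),
                   score, clusters$summit, clusters$mean_density, er)
  writeLines(lines, path)
  invisible(path)
}
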