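# Strand cross-correlation (characteristic protected-fragment size) and
# same-strand auto-correlation with Fourier periodicity analysis.
#
# Correlations are Pearson correlations of the full per-position count
# vectors at integer lags. On a circular genome the lagged vector wraps and
# the whole lag family is computed at once via the FFT; on a linear genome
# the vectors are truncated to their overlap.

correlation_profile <- function(lags, raw, window, kind, per_strand = NULL) {
  structure(list(
    lags = lags, raw = raw,
    smoothed = smooth_running_window(raw, window),
    window = window, kind = kind, per_strand = per_strand
  ), class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile (%s): lags 0-%d, %d-bp smoothing window\n",
              x$kind, max(x$lags), x$window))
  i <- which.max(x$smoothed)
  cat(sprintf("  smoothed maximum %.4g at lag %d\n", x$smoothed[i], x$lags[i]))
  invisible(x)
}

# Pearson correlation of x against y shifted left by each lag in 0..max_lag.
lagged_pearson <- function(x, y, max_lag, circular) {
  n <- length(x)
  if (circular) {
    sx <- sd_pop(x)
    sy <- sd_pop(y)
    if (sx == 0 || sy == 0)
      stop("undefined correlation: a strand has zero count variance", call. = FALSE)
    cc <- circular_cross_sum(x, y)[seq_len(max_lag + 1L)]
    (cc / n - mean(x) * mean(y)) / (sx * sy)
  } else {
    vapply(0:max_lag, function(d) {
      xi <- x[seq_len(n - d)]
      yi <- y[seq.int(d + 1L, n)]
      if (stats::sd(xi) == 0 || stats::sd(yi) == 0)
        stop("undefined correlation: a strand has zero count variance", call. = FALSE)
      stats::cor(xi, yi)
    }, numeric(1))
  }
}

#' Strand cross-correlation of a tag set
#'
#' Correlates plus-strand tag counts against minus-strand counts shifted by
#' each lag. Because paired 5'-end tags from one double-stranded fragment
#' map to opposite strands one fragment length apart, the non-technical
#' maximum of this profile estimates the characteristic protected-fragment
#' size.
#'
#' @param tags a [tag_set()] with at least two occupied positions per strand.
#' @param max_lag largest lag in bp.
#' @param window running-window width in bp for the smoothed profile.
#' @return a `correlation_profile` with fields `lags` (0..`max_lag`), `raw`,
#'   `smoothed`, `window` and `kind = "cross"`.
#' @export
strand_cross_correlation <- function(tags, max_lag = 500, window = 25) {
  stopifnot(inherits(tags, "tag_set"))
  if (sum(tags$counts_plus > 0) < 2 || sum(tags$counts_minus > 0) < 2)
    stop("each strand needs at least 2 occupied positions", call. = FALSE)
  raw <- lagged_pearson(tags$counts_plus, tags$counts_minus, max_lag, tags$circular)
  correlation_profile(0:max_lag, raw, window, "cross")
}

#' Same-strand auto-correlation of a tag set
#'
#' Computes the Pearson autocorrelation of each strand's counts at every lag
#' and averages the two strands (each strand also returned separately).
#' Periodic spacing of protected fragments appears as regularly spaced local
#' maxima in this profile.
#'
#' @inheritParams strand_cross_correlation
#' @return a `correlation_profile` with `kind = "auto"`; `per_strand` holds
#'   the two per-strand raw profiles as a 2-column matrix.
#' @export
strand_auto_correlation <- function(tags, max_lag = 1000, window = 25) {
  stopifnot(inherits(tags, "tag_set"))
  per <- list(`+` = NULL, `-` = NULL)
  for (s in c("+", "-")) {
    v <- if (s == "+") tags$counts_plus else tags$counts_minus
    per[[s]] <- tryCatch(lagged_pearson(v, v, max_lag, tags$circular),
                         error = function(e) NULL)
    if (is.null(per[[s]]))
      warning(sprintf("strand %s has zero count variance and is excluded", s),
              call. = FALSE)
  }
  used <- !vapply(per, is.null, logical(1))
  if (!any(used))
    stop("both strands have zero count variance", call. = FALSE)
  mat <- do.call(cbind, per[used])
  raw <- rowMeans(mat)
  correlation_profile(0:max_lag, raw, window, "auto", per_strand = mat)
}

#' Estimate the characteristic fragment size from a cross-correlation profile
#'
#' Finds the maximum of the smoothed cross-correlation outside the technical
#' band around the read length (a peak at the read length arises from the
#' unique-alignment requirement, not from fragment structure). A candidate
#' must be a genuine peak, not the shoulder of the excluded technical peak
#' and not the top of a broad noise plateau: it must be a local maximum of
#' the smoothed profile, and it must rise above the median of the searched
#' profile by at least `prominence` of its height above the profile
#' minimum. Profiles without such a peak - e.g. the naked-DNA control,
#' whose fragment lengths have no characteristic value and whose
#' cross-correlation is a flat plateau - raise a `nucfoot_no_estimate`
#' error.
#'
#' @param profile a `correlation_profile` of kind `"cross"`.
#' @param read_length sequenced tag length in bp; the band
#'   `read_length +/- exclusion_halfwidth` is excluded from the search.
#' @param exclusion_halfwidth half-width in bp of the excluded band.
#' @param min_lag smallest lag considered.
#' @param prominence required rise of the peak above the searched profile's
#'   median, as a fraction of its height above the profile minimum.
#' @return a `fragment_size_estimate`: `fragment_size` (= `peak_lag`),
#'   `peak_lag`, `peak_value`, `technical_peak_lag` (or `NA`),
#'   `excluded_band`.
#' @export
estimate_fragment_size <- function(profile, read_length = 36, exclusion_halfwidth = 5,
                                   min_lag = 20, prominence = 0.5) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (!identical(profile$kind, "cross"))
    stop("fragment size is estimated from a cross-correlation profile", call. = FALSE)
  s <- profile$smoothed
  lags <- profile$lags
  band <- c(read_length - exclusion_halfwidth, read_length + exclusion_halfwidth)
  in_band <- lags >= band[1] & lags <= band[2]
  search <- lags >= min_lag & !in_band
  if (!any(search)) stop("no lags left to search", call. = FALSE)

  cand <- which(search)[which.max(s[search])]
  peak_lag <- lags[cand]
  height <- s[cand] - min(s[search])
  is_local_max <- cand > 1L && cand < length(s) &&
    s[cand] >= s[cand - 1L] && s[cand] >= s[cand + 1L]
  prominent <- height > 0 &&
    (s[cand] - stats::median(s[search])) >= prominence * height
  if (!is_local_max || !prominent) {
    stop(structure(class = c("nucfoot_no_estimate", "error", "condition"),
                   list(message = paste0(
                     "no fragment-size estimate: no prominent cross-correlation peak ",
                     "outside the read-length band (control-like sample)"),
                     call = NULL)))
  }

  technical <- NA_integer_
  if (any(in_band)) {
    b <- which(in_band)[which.max(s[in_band])]
    edges <- c(match(band[1] - 1L, lags), match(band[2] + 1L, lags))
    edge_vals <- s[edges[!is.na(edges)]]
    if (length(edge_vals) && all(s[b] >= edge_vals)) technical <- lags[b]
  }

  structure(list(
    fragment_size = peak_lag,
    peak_lag = peak_lag,
    peak_value = s[cand],
    technical_peak_lag = technical,
    excluded_band = band
  ), class = "fragment_size_estimate")
}

#' @export
print.fragment_size_estimate <- function(x, ...) {
  cat(sprintf("fragment_size_estimate: %d bp (smoothed cross-correlation peak %.4g)\n",
              x$fragment_size, x$peak_value))
  if (!is.na(x$technical_peak_lag))
    cat(sprintf("  technical read-length peak at %d bp (band %d-%d excluded)\n",
                x$technical_peak_lag, x$excluded_band[1], x$excluded_band[2]))
  invisible(x)
}

#' Fourier periodogram of a correlation profile
#'
#' Mean-subtracts the raw profile over lags 1..max and computes its discrete
#' Fourier power spectrum, mapped from frequency to period. The dominant
#' period is the power maximum restricted to `period_range`. At
#' `oversample = 1` the power at each Fourier frequency equals the explained
#' sum of squares of a least-squares sinusoid fit at that frequency;
#' `oversample > 1` zero-pads the profile to refine the period grid.
#'
#' @param profile a `correlation_profile` (typically kind `"auto"`).
#' @param period_range `c(min, max)` period in bp searched for the dominant
#'   period.
#' @param oversample integer zero-padding factor for the frequency grid.
#' @return a `periodogram_result`: `periods` (bp, decreasing), `power`,
#'   `dominant_period`, `period_range`, `n_lags`.
#' @export
periodogram <- function(profile, period_range = c(50, 500), oversample = 4) {
  stopifnot(inherits(profile, "correlation_profile"))
  y <- profile$raw[profile$lags >= 1]
  n <- length(y)
  if (period_range[2] > n / 2) {
    warning(sprintf(
      "profile has %d lags, fewer than twice the maximum period; searching up to %d bp",
      n, floor(n / 2)), call. = FALSE)
    period_range[2] <- floor(n / 2)
  }
  y <- y - mean(y)
  if (sd_pop(y) == 0)
    stop("constant correlation profile: periodogram is flat, no dominant period",
         call. = FALSE)
  npad <- n * max(1L, as.integer(oversample))
  ypad <- c(y, numeric(npad - n))
  spec <- Mod(stats::fft(ypad))^2 * 2 / n
  k <- seq_len(floor(npad / 2))
  periods <- npad / k
  power <- spec[k + 1L]
  in_range <- periods >= period_range[1] & periods <= period_range[2]
  if (!any(in_range))
    stop("no Fourier frequencies fall in the requested period range", call. = FALSE)
  dom <- periods[in_range][which.max(power[in_range])]
  structure(list(
    periods = periods, power = power,
    dominant_period = dom, period_range = period_range,
    n_lags = n, oversample = oversample
  ), class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf("periodogram: dominant period %.1f bp in range %d-%d bp (%d lags)\n",
              x$dominant_period, x$period_range[1], x$period_range[2], x$n_lags))
  invisible(x)
}

#' Write a correlation profile as TSV
#' @param profile a `correlation_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_profile <- function(profile, path) {
  utils::write.table(
    data.frame(lag = profile$lags, raw = profile$raw, smoothed = profile$smoothed),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a periodogram as TSV
#' @param pg a `periodogram_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_periodogram <- function(pg, path) {
  utils::write.table(data.frame(period = pg$periods, power = pg$power),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
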