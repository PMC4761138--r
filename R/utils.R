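# Shared numeric helpers: circular arithmetic, FFT correlation machinery,
# running-window smoothing.

#' Minimal distance between positions on a circular genome
#'
#' @param a,b integer position vectors (0-based), recycled.
#' @param genome_length circle length in bp.
#' @return integer vector of minimal circular distances.
#' @keywords internal
circ_dist <- function(a, b, genome_length) {
  d <- abs(a - b) %% genome_length
  pmin(d, genome_length - d)
}

#' Rotate a vector left by d positions (circular shift)
#' @keywords internal
rotate_vec <- function(x, d) {
  n <- length(x)
  d <- d %% n
  if (d == 0L) return(x)
  c(x[(d + 1L):n], x[1L:d])
}

# Circular cross-covariance sums via FFT.
# Returns C with C[d + 1] = sum_i x[i] * y[(i + d) mod n], d = 0..n-1.
circular_cross_sum <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y), inverse = TRUE)) / n
}

# Population standard deviation (divides by n, not n - 1).
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Centered running-window (boxcar) mean
#'
#' Smooths a numeric vector with a centered moving average. Even window
#' widths are rounded up to the next odd integer so the window stays
#' centered; at the edges the window is truncated to the available values.
#'
#' @param values numeric vector.
#' @param window window width in positions; values `< 1` are an error,
#'   `1` returns the input unchanged.
#' @return numeric vector of the same length as `values`.
#' @examples
#' smooth_running_window(c(0, 0, 3, 0, 0), 3) # 0 1 1 1 0
#' @export
smooth_running_window <- function(values, window) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) || window < 1)
    stop("'window' must be a single number >= 1", call. = FALSE)
  n <- length(values)
  window <- as.integer(round(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) window <- if (n %% 2L == 1L) n else n - 1L
  if (window <= 1L) return(values)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic per-stage substream seeds derived from one global seed.
# Stages are numbered so that each generator can be re-run independently
# of the others while remaining a pure function of (config, seed).
stage_seed <- function(seed, stage) {
  p <- 2147483647 # 2^31 - 1 (Mersenne prime), keeps the result a valid R integer
  as.integer((as.numeric(seed) + stage * 1299709) %% p)
}

# Configuration error naming the offending field.
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Sequence coercion: accepts a single character string, a character vector of
# single bases, or a Biostrings::DNAString; returns an uppercase base vector.
as_base_vector <- function(sequence) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet")) {
    if (inherits(sequence, "DNAStringSet")) {
      if (length(sequence) != 1L)
        stop("multi-sequence input: supply a single sequence", call. = FALSE)
      sequence <- sequence[[1L]]
    }
    return(strsplit(as.character(sequence), "", fixed = TRUE)[[1L]])
  }
  if (is.character(sequence)) {
    if (length(sequence) == 1L && nchar(sequence) > 1L)
      return(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]])
    return(toupper(sequence))
  }
  stop("'sequence' must be a character string or a DNAString", call. = FALSE)
}
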