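# ChIP-signal association: genome-wide z-score normalization and the average
# signal profile around cluster centers.

#' Z-score-normalize a genome-wide signal track
#'
#' Standardizes a per-position signal to zero mean and unit (population)
#' standard deviation over all genome positions, putting tracks from
#' different experiments on a comparable "relative signal" scale.
#'
#' @param values numeric vector, one value per genome position.
#' @return a `signal_track`: `values`, `zvalues`, `mean`, `sd`.
#' @export
zscore_track <- function(values) {
  if (length(values) < 2) stop("at least two positions are required", call. = FALSE)
  mu <- mean(values)
  sigma <- sd_pop(values)
  if (sigma == 0)
    stop("degenerate track: all values are equal, z-scores undefined", call. = FALSE)
  structure(list(values = values, zvalues = (values - mu) / sigma,
                 mean = mu, sd = sigma), class = "signal_track")
}

#' Average signal profile around a set of points
#'
#' Computes the mean z-scored signal at each offset in `[-flank, +flank]`
#' over all anchor points (typically cluster centers), wrapping on a
#' circular genome. Strandless: no orientation is applied.
#'
#' @param points integer vector of 0-based anchor positions.
#' @param track a `signal_track` from [zscore_track()].
#' @param flank half-width of the window in bp.
#' @param circular logical; wrap offsets around the genome.
#' @return a `meta_profile` whose `mean_value` is the mean z-score per
#'   offset (`smoothed` is identical; no smoothing is applied).
#' @export
profile_around <- function(points, track, flank = 1000, circular = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  if (length(points) < 1) stop("at least one point is required", call. = FALSE)
  G <- length(track$zvalues)
  offsets <- -flank:flank
  idx <- outer(as.integer(points), offsets, `+`)
  if (circular) {
    idx <- ((idx %% G) + G) %% G
  } else {
    if (any(idx < 0 | idx >= G))
      stop("points closer than the flank to a linear genome boundary", call. = FALSE)
  }
  m <- matrix(track$zvalues[idx + 1L], nrow = length(points))
  raw <- colMeans(m)
  meta_profile(offsets, raw, raw, length(points), NA_integer_, "point")
}

#' Cluster center positions
#'
#' Midpoints of cluster intervals, modulo the genome length for clusters
#' wrapping the origin.
#'
#' @param clusters a `nucfoot_clusters` data.frame.
#' @param genome_length genome size in bp.
#' @return integer vector of 0-based center positions.
#' @export
cluster_centers <- function(clusters, genome_length) {
  as.integer(((clusters$start + clusters$end) %/% 2L) %% genome_length)
}
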