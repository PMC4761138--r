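# Strandless fragment centers and strand-oriented aggregate (metagene)
# profiles around gene starts and ends.

#' Convert tags to strandless fragment centers
#'
#' Shifts each tag 5'-end by half the characteristic fragment size towards
#' the fragment 3'-end: plus-strand tags move right, minus-strand tags move
#' left. The resulting positions approximate digestion-fragment centers and
#' carry no strand association.
#'
#' @param tags a [tag_set()].
#' @param fragment_size characteristic fragment size in bp (>= 2), e.g. from
#'   [estimate_fragment_size()].
#' @return a `center_set`: `counts` (per-position center counts),
#'   `genome_length`, `circular`, `shift_used`, `n_centers`. On a circular
#'   genome the number of centers equals the number of tags; on a linear
#'   genome out-of-range centers are dropped and counted in `n_dropped`.
#' @export
to_fragment_centers <- function(tags, fragment_size) {
  stopifnot(inherits(tags, "tag_set"))
  if (!is.numeric(fragment_size) || fragment_size < 2)
    stop("'fragment_size' must be >= 2", call. = FALSE)
  G <- tags$genome_length
  shift <- as.integer(round(fragment_size / 2))
  pp <- rep.int(which(tags$counts_plus > 0) - 1L,
                tags$counts_plus[tags$counts_plus > 0]) + shift
  pm <- rep.int(which(tags$counts_minus > 0) - 1L,
                tags$counts_minus[tags$counts_minus > 0]) - shift
  pos <- c(pp, pm)
  n_dropped <- 0L
  if (tags$circular) {
    pos <- pos %% G
  } else {
    keep <- pos >= 0 & pos < G
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      warning(sprintf("%d centers fell outside the linear genome and were dropped",
                      n_dropped), call. = FALSE)
    pos <- pos[keep]
  }
  structure(list(
    counts = tabulate(pos + 1L, nbins = G),
    genome_length = G,
    circular = tags$circular,
    shift_used = shift,
    n_centers = length(pos),
    n_dropped = n_dropped
  ), class = "center_set")
}

#' @export
print.center_set <- function(x, ...) {
  cat(sprintf("center_set: %s fragment centers (5'-ends shifted by %d bp) on %s bp\n",
              format(x$n_centers, big.mark = ","), x$shift_used,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

meta_profile <- function(offsets, raw, smoothed, n_genes, window, anchor) {
  structure(list(offsets = offsets, mean_value = raw, smoothed = smoothed,
                 n_genes = n_genes, smoothing_window = window, anchor = anchor),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile at %s over %d genes, offsets %d..%d\n",
              x$anchor, x$n_genes, min(x$offsets), max(x$offsets)))
  invisible(x)
}

# Extract a genes x offsets matrix of values, oriented so positive offsets
# point downstream of transcription. `values` is a per-position vector.
extract_oriented <- function(values, genes, anchor, flank, circular) {
  G <- length(values)
  anchor_pos <- if (anchor == "tss") genes$tss else genes$tes
  sgn <- ifelse(genes$strand == "+", 1L, -1L)
  if (!circular) {
    ok <- anchor_pos - flank >= 0 & anchor_pos + flank < G
    if (any(!ok))
      warning(sprintf("%d genes closer than the flank to a genome boundary were skipped",
                      sum(!ok)), call. = FALSE)
    anchor_pos <- anchor_pos[ok]; sgn <- sgn[ok]
  }
  if (length(anchor_pos) == 0) stop("no usable genes", call. = FALSE)
  offsets <- -flank:flank
  idx <- outer(sgn, offsets) + anchor_pos # genes x offsets
  idx <- ((idx %% G) + G) %% G
  matrix(values[idx + 1L], nrow = length(anchor_pos))
}

#' Aggregate fragment-center density around gene anchors
#'
#' For each gene, extracts center counts in a window around the TSS or TES,
#' flips minus-strand genes so positive offsets point downstream of
#' transcription, and averages over genes. Accessibility of gene boundaries
#' to digestion appears as a dip centered on the anchor.
#'
#' @param centers a `center_set` from [to_fragment_centers()].
#' @param genes annotation data.frame from [read_annotations()] (or simulator
#'   truth).
#' @param anchor `"tss"` or `"tes"`.
#' @param flank half-width of the window in bp.
#' @param window running-window width in bp for smoothing.
#' @return a `meta_profile`: `offsets`, `mean_value` (raw), `smoothed`,
#'   `n_genes`, `smoothing_window`, `anchor`.
#' @export
metagene_profile <- function(centers, genes, anchor = c("tss", "tes"),
                             flank = 500, window = 50) {
  stopifnot(inherits(centers, "center_set"))
  anchor <- match.arg(anchor)
  if (nrow(genes) < 1) stop("at least one gene is required", call. = FALSE)
  m <- extract_oriented(centers$counts, genes, anchor, flank, centers$circular)
  raw <- colMeans(m)
  meta_profile(-flank:flank, raw, smooth_running_window(raw, window),
               nrow(m), window, anchor)
}

#' GC-content profile around gene anchors
#'
#' Per offset, the fraction of genes whose strand-oriented aligned base is G
#' or C.
#'
#' @param sequence genome sequence (string or base vector).
#' @inheritParams metagene_profile
#' @param circular logical; genome circularity.
#' @return a `meta_profile` of GC fractions.
#' @export
gc_metaprofile <- function(sequence, genes, anchor = c("tss", "tes"),
                           flank = 500, window = 50, circular = TRUE) {
  anchor <- match.arg(anchor)
  if (nrow(genes) < 1) stop("at least one gene is required", call. = FALSE)
  gc <- as.numeric(as_base_vector(sequence) %in% c("G", "C"))
  m <- extract_oriented(gc, genes, anchor, flank, circular)
  raw <- colMeans(m)
  meta_profile(-flank:flank, raw, smooth_running_window(raw, window),
               nrow(m), window, anchor)
}

#' A-tract frequency profile around gene starts
#'
#' Per offset, the fraction of genes with an A-tract covering the aligned
#' position; a loess-smoothed curve is returned alongside the raw profile.
#'
#' @param atracts tract table from [find_atracts()].
#' @param genes annotation data.frame.
#' @param genome_length genome size in bp.
#' @param flank half-width of the window in bp.
#' @param loess_span span of the loess smoother (fraction of the window).
#' @param circular logical; genome circularity.
#' @return a `meta_profile`; `smoothed` is the loess fit.
#' @export
atract_metaprofile <- function(atracts, genes, genome_length, flank = 500,
                               loess_span = 0.1, circular = TRUE) {
  if (nrow(genes) < 1) stop("at least one gene is required", call. = FALSE)
  cov <- numeric(genome_length)
  if (nrow(atracts) > 0) {
    idx <- unlist(mapply(seq.int, atracts$start + 1L, atracts$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    cov[idx] <- 1
  }
  m <- extract_oriented(cov, genes, "tss", flank, circular)
  raw <- colMeans(m)
  offsets <- -flank:flank
  sm <- stats::predict(stats::loess(raw ~ offsets, span = loess_span,
                                    degree = 2, family = "gaussian"))
  meta_profile(offsets, raw, sm, nrow(m), NA_integer_, "tss")
}

#' Write a metagene profile as TSV
#' @param profile a `meta_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_profile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offsets, raw = profile$mean_value,
               smoothed = profile$smoothed, n_genes = profile$n_genes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
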