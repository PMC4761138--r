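# A-tract (poly(dA:dT)) enumeration and sequence statistics: per-length
# frequency spectra over region sets, genome-to-random ratios over shuffled
# genomes, and GC content.

#' Find A-tracts in a sequence
#'
#' An A-tract is a maximal run of A immediately followed by a maximal run of
#' T (either run may be empty; a TpA step is never internal). Tracts are
#' reported when their total length n(A) + m(T) lies in
#' `[min_len, max_len]`; longer runs are excluded entirely, not truncated,
#' since the definition bounds the total length itself. `N` and any non-A/T
#' base break runs. The scan is left-to-right over the run-length encoding
#' of the sequence, so reported tracts are maximal, non-overlapping and
#' sorted.
#'
#' @param sequence character string, base vector or `DNAString`.
#' @param min_len,max_len inclusive bounds on tract length in bp.
#' @return a data.frame of class `atract_table` with columns `start`, `end`
#'   (0-based half-open), `nA`, `nT`, `length`.
#' @examples
#' find_atracts("CCAAATTTCC") # one tract, nA = 3, nT = 3
#' find_atracts("ATATAT")     # none: every maximal AnTm is shorter than 3
#' @export
find_atracts <- function(sequence, min_len = 3, max_len = 10) {
  seqv <- as_base_vector(sequence)
  sym <- ifelse(seqv == "A", "A", ifelse(seqv == "T", "T", "x"))
  r <- rle(sym)
  n_runs <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths # 0-based

  iA <- which(r$values == "A")
  followed_by_T <- iA < n_runs & r$values[pmin(iA + 1L, n_runs)] == "T"
  a_start <- run_start[iA]
  a_nA <- r$lengths[iA]
  a_nT <- ifelse(followed_by_T, r$lengths[pmin(iA + 1L, n_runs)], 0L)

  iT <- which(r$values == "T")
  lone_T <- !(iT > 1L & r$values[pmax(iT - 1L, 1L)] == "A")
  t_start <- run_start[iT[lone_T]]
  t_nT <- r$lengths[iT[lone_T]]

  out <- data.frame(
    start = c(a_start, t_start),
    nA = c(a_nA, integer(length(t_start))),
    nT = c(a_nT, t_nT)
  )
  out$length <- out$nA + out$nT
  out$end <- out$start + out$length
  out <- out[out$length >= min_len & out$length <= max_len,
             c("start", "end", "nA", "nT", "length"), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("atract_table", "data.frame")
  out
}

#' Per-length A-tract frequencies over a region set
#'
#' Counts tracts per length and normalizes by the total region length to
#' tracts per kb. By default a tract belongs to a region when its midpoint
#' falls inside it; `"any"` (any overlap) and `"within"` (full containment)
#' are available as alternatives.
#'
#' @param tracts an `atract_table` from [find_atracts()].
#' @param genome_length genome size in bp.
#' @param regions optional data.frame with 0-based half-open `start`, `end`
#'   columns; `NULL` means the whole genome.
#' @param min_len,max_len tract length bounds for the spectrum.
#' @param membership region-membership rule for a tract.
#' @return a `tract_stats` object: `lengths`, `counts_by_length`,
#'   `frequency_per_kb`, `region_bp`.
#' @export
tract_frequency_spectrum <- function(tracts, genome_length, regions = NULL,
                                     min_len = 3, max_len = 10,
                                     membership = c("midpoint", "any", "within")) {
  membership <- match.arg(membership)
  lens <- min_len:max_len
  if (is.null(regions)) {
    region_bp <- genome_length
    sel <- rep(TRUE, nrow(tracts))
  } else {
    if (nrow(regions) == 0 || sum(regions$end - regions$start) == 0)
      stop("empty region set", call. = FALSE)
    reg <- IRanges::reduce(IRanges::IRanges(
      start = (regions$start %% genome_length) + 1L,
      end = ((regions$end - 1L) %% genome_length) + 1L))
    region_bp <- sum(IRanges::width(reg))
    tr <- switch(membership,
      midpoint = IRanges::IRanges(start = (tracts$start + tracts$end) %/% 2L + 1L,
                                  width = 1L),
      IRanges::IRanges(start = tracts$start + 1L, end = tracts$end))
    hits <- IRanges::overlapsAny(tr, reg,
                                 type = if (membership == "within") "within" else "any")
    sel <- hits
  }
  counts <- vapply(lens, function(L) sum(tracts$length[sel] == L), numeric(1))
  structure(list(
    lengths = lens,
    counts_by_length = counts,
    frequency_per_kb = counts / (region_bp / 1000),
    region_bp = region_bp
  ), class = "tract_stats")
}

#' Genome-to-random A-tract ratio over shuffled genomes
#'
#' For each tract length, the ratio of the observed tract count to the mean
#' count over `n_rand` independent uniform permutations of the genome's own
#' bases. Shuffling preserves the mononucleotide composition exactly;
#' i.i.d. resampling at the same composition is available as an option. A
#' zero mean null count yields an infinite ratio (reported with the counts
#' for context).
#'
#' @param sequence genome sequence (string, base vector or `DNAString`).
#' @param n_rand number of randomized genomes.
#' @param seed integer seed.
#' @param min_len,max_len tract length bounds.
#' @param method `"shuffle"` (permutation) or `"iid"` (resampling).
#' @return a `tract_stats` object with `genome_to_random_ratio`,
#'   `null_mean_counts`, `n_randomizations`, `randomization_seed` in
#'   addition to the observed spectrum fields.
#' @export
genome_to_random_ratio <- function(sequence, n_rand = 15, seed = 1,
                                   min_len = 3, max_len = 10,
                                   method = c("shuffle", "iid")) {
  method <- match.arg(method)
  seqv <- as_base_vector(sequence)
  G <- length(seqv)
  if (G < 1000) stop("sequence too short for stable ratios (need >= 1 kb)", call. = FALSE)
  lens <- min_len:max_len
  count_by_len <- function(v) {
    tr <- find_atracts(v, min_len, max_len)
    vapply(lens, function(L) sum(tr$length == L), numeric(1))
  }
  obs <- count_by_len(seqv)
  set.seed(seed)
  null_counts <- matrix(0, nrow = n_rand, ncol = length(lens))
  for (r in seq_len(n_rand)) {
    rnd <- if (method == "shuffle") sample(seqv) else
      sample(c("A", "C", "G", "T"), G, replace = TRUE,
             prob = tabulate(factor(seqv, c("A", "C", "G", "T")), 4L) / G)
    null_counts[r, ] <- count_by_len(rnd)
  }
  null_mean <- colMeans(null_counts)
  ratio <- ifelse(null_mean > 0, obs / null_mean, ifelse(obs > 0, Inf, NA_real_))
  structure(list(
    lengths = lens,
    counts_by_length = obs,
    frequency_per_kb = obs / (G / 1000),
    region_bp = G,
    genome_to_random_ratio = ratio,
    null_mean_counts = null_mean,
    n_randomizations = n_rand,
    randomization_seed = seed,
    method = method
  ), class = "tract_stats")
}

#' @export
print.tract_stats <- function(x, ...) {
  cat(sprintf("tract_stats over %s bp:\n", format(x$region_bp, big.mark = ",")))
  df <- data.frame(length = x$lengths, count = x$counts_by_length,
                   per_kb = round(x$frequency_per_kb, 4))
  if (!is.null(x$genome_to_random_ratio))
    df$genome_to_random <- round(x$genome_to_random_ratio, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write tract statistics as TSV
#' @param stats_obj a `tract_stats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tract_stats <- function(stats_obj, path) {
  df <- data.frame(length = stats_obj$lengths,
                   count = stats_obj$counts_by_length,
                   frequency_per_kb = stats_obj$frequency_per_kb)
  if (!is.null(stats_obj$genome_to_random_ratio)) {
    df$genome_to_random_ratio <- stats_obj$genome_to_random_ratio
    df$null_mean_count <- stats_obj$null_mean_counts
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write A-tracts as BED4
#' @param tracts an `atract_table`.
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_atracts_bed <- function(tracts, path, chrom = "chr") {
  lines <- sprintf("%s\t%d\t%d\tA%dT%d", chrom, tracts$start, tracts$end,
                   tracts$nA, tracts$nT)
  writeLines(lines, path)
  invisible(path)
}

#' GC content of a sequence or region set
#'
#' Fraction of G+C among unambiguous bases; `N` is excluded from the
#' denominator.
#'
#' @param sequence genome sequence (string, base vector or `DNAString`).
#' @param regions optional data.frame of 0-based half-open `start`, `end`
#'   intervals; `NULL` means the whole sequence.
#' @return GC fraction.
#' @export
gc_content <- function(sequence, regions = NULL) {
  seqv <- as_base_vector(sequence)
  if (!is.null(regions)) {
    if (nrow(regions) == 0) stop("empty region set", call. = FALSE)
    G <- length(seqv)
    idx <- unique(unlist(mapply(function(s, e) (s:(e - 1L)) %% G,
                                regions$start, regions$end, SIMPLIFY = FALSE)))
    seqv <- seqv[idx + 1L]
  }
  gc <- sum(seqv %in% c("G", "C"))
  at <- sum(seqv %in% c("A", "T"))
  if (gc + at == 0) stop("no unambiguous bases in the region set", call. = FALSE)
  gc / (gc + at)
}
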