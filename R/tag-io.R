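# Reading aligned digestion tags and gene annotations, the anomalous-position
# filter, and the on-disk representations (BED6, SAM/BAM, GFF3, bedGraph).

#' Construct a tag set
#'
#' A tag set stores, per strand, the number of digestion-fragment 5'-ends
#' mapped to each genome position. It is the central observable of the
#' pipeline: all correlation, profile and cluster analyses start from it.
#'
#' @param counts_plus,counts_minus non-negative integer vectors of length
#'   `genome_length`: tag 5'-end counts per position for the plus and minus
#'   strand.
#' @param genome_length genome size in bp.
#' @param circular logical; `TRUE` for a circular chromosome.
#' @param tag_length sequenced tag length in bp.
#' @return an object of class `tag_set`.
#' @export
tag_set <- function(counts_plus, counts_minus, genome_length = length(counts_plus),
                    circular = TRUE, tag_length = 36) {
  counts_plus <- as.numeric(counts_plus)
  counts_minus <- as.numeric(counts_minus)
  if (length(counts_plus) != genome_length || length(counts_minus) != genome_length)
    stop("count vectors must have length 'genome_length'", call. = FALSE)
  if (any(counts_plus < 0) || any(counts_minus < 0))
    stop("tag counts must be non-negative", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length),
    circular = isTRUE(circular),
    counts_plus = counts_plus,
    counts_minus = counts_minus,
    tag_length = as.integer(tag_length),
    n_tags = sum(counts_plus) + sum(counts_minus)
  ), class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %s tags (%s +, %s -) on a %s %s-bp genome, %d-bp tags\n",
              format(x$n_tags, big.mark = ","),
              format(sum(x$counts_plus), big.mark = ","),
              format(sum(x$counts_minus), big.mark = ","),
              if (x$circular) "circular" else "linear",
              format(x$genome_length, big.mark = ","), x$tag_length))
  invisible(x)
}

#' Read aligned tags into a tag set
#'
#' Each input record contributes one count at the position of its 5'-end:
#' for plus-strand records the leftmost aligned base, for minus-strand
#' records the rightmost aligned base (standard aligner semantics). Reads
#' BED6 (the interval is the aligned tag) or SAM/BAM (SAM files are
#' converted in a temporary directory via [Rsamtools::asBam()]).
#' Uniqueness and mismatch filtering are the upstream aligner's job; for
#' SAM/BAM input a mapping-quality floor is available as a proxy.
#'
#' @param path path to a BED6, SAM or BAM file.
#' @param genome_length genome size in bp; records outside `[0, genome_length)`
#'   are an error.
#' @param format `"auto"` (by file extension), `"bed"`, `"sam"` or `"bam"`.
#' @param circular logical, stored on the returned tag set.
#' @param tag_length tag length in bp, stored on the returned tag set.
#' @param min_mapq minimum mapping quality for SAM/BAM records (ignored for
#'   BED input).
#' @return a [tag_set()].
#' @export
read_tags <- function(path, genome_length, format = c("auto", "bed", "sam", "bam"),
                      circular = TRUE, tag_length = 36, min_mapq = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop(sprintf("cannot infer tag format from extension '.%s'", ext),
                          call. = FALSE))
  }
  if (format == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop(sprintf("parse error in '%s': %s",
                                                    path, conditionMessage(e)), call. = FALSE))
    str <- as.character(GenomicRanges::strand(gr))
    if (any(str == "*"))
      stop(sprintf("parse error in '%s': %d records lack a strand",
                   path, sum(str == "*")), call. = FALSE)
    pos5 <- ifelse(str == "+", GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr) - 1L)
  } else {
    bam <- path
    if (format == "sam")
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("strand", "pos", "cigar", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
    rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
    keep <- !is.na(rec$pos) & (is.na(rec$mapq) | rec$mapq >= min_mapq)
    str <- as.character(rec$strand)[keep]
    pos1 <- rec$pos[keep]
    width <- cigar_reference_width(rec$cigar[keep])
    pos5 <- ifelse(str == "+", pos1 - 1L, pos1 - 1L + width - 1L)
  }
  oob <- pos5 < 0 | pos5 >= genome_length
  if (any(oob)) {
    if (!circular)
      stop(sprintf("coordinate error: %d records outside [0, %d)", sum(oob), genome_length),
           call. = FALSE)
    pos5 <- pos5 %% genome_length
  }
  cp <- tabulate(pos5[str == "+"] + 1L, nbins = genome_length)
  cm <- tabulate(pos5[str == "-"] + 1L, nbins = genome_length)
  tag_set(cp, cm, genome_length, circular = circular, tag_length = tag_length)
}

# Reference-space width of CIGAR strings (sum of M, D, N, =, X operation
# lengths). Small by design: the reader needs nothing else from the CIGAR.
cigar_reference_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
    parts <- regmatches(cg, list(ops))[[1L]]
    op <- substr(parts, nchar(parts), nchar(parts))
    len <- as.integer(substr(parts, 1L, nchar(parts) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a tag set as BED6
#'
#' One record per tag; the interval is the aligned `tag_length`-bp tag, with
#' the 5'-end at `chromStart` for plus-strand and `chromEnd - 1` for
#' minus-strand records. Intervals are clipped to the genome so the file is
#' valid BED; the 5'-end coordinate is always preserved.
#'
#' @param tags a [tag_set()].
#' @param path output path.
#' @param chrom chromosome name used in the BED records.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path, chrom = "chr") {
  stopifnot(inherits(tags, "tag_set"))
  G <- tags$genome_length
  L <- tags$tag_length
  pp <- rep.int(which(tags$counts_plus > 0) - 1L, tags$counts_plus[tags$counts_plus > 0])
  pm <- rep.int(which(tags$counts_minus > 0) - 1L, tags$counts_minus[tags$counts_minus > 0])
  start <- c(pp, pmax(pm - L + 1L, 0L))
  end <- c(pmin(pp + L, G), pm + 1L)
  strand <- rep(c("+", "-"), c(length(pp), length(pm)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end),
                               strand = strand)
  gr$name <- "."
  gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Remove anomalous tag pile-ups (Z-score filter)
#'
#' Positions carrying implausibly many tags - typically amplification
#' artifacts - are removed by a per-strand Z-score test. For each strand the
#' mean and standard deviation of counts are computed over occupied
#' positions (count >= 1); any position whose count exceeds the mean by more
#' than `z_threshold` standard deviations has its count set to zero.
#' Restricting the statistics to occupied positions is deliberate: over all
#' positions the genome-wide mean is far below 1 and the filter would flag
#' nearly every duplicated position, defeating its purpose. Both choices are
#' exposed as flags.
#'
#' @param tags a [tag_set()].
#' @param z_threshold Z-score above which a position is anomalous.
#' @param pool_strands compute one mean/sd over both strands instead of per
#'   strand.
#' @param include_zeros include unoccupied positions in the mean/sd.
#' @return a list with elements `tags` (filtered [tag_set()]) and `report`
#'   (a `qc_report`: threshold, per-strand statistics, removed positions and
#'   removed tag count).
#' @export
filter_anomalous_positions <- function(tags, z_threshold = 7,
                                       pool_strands = FALSE, include_zeros = FALSE) {
  stopifnot(inherits(tags, "tag_set"))
  if (tags$n_tags <= 0) stop("tag set is empty", call. = FALSE)
  counts <- list(`+` = tags$counts_plus, `-` = tags$counts_minus)

  stat_basis <- function(v) if (include_zeros) v else v[v >= 1]
  if (pool_strands) {
    basis <- stat_basis(c(counts$`+`, counts$`-`))
    mu <- rep(mean(basis), 2L)
    sdev <- rep(sd_basis(basis), 2L)
  } else {
    mu <- unname(vapply(counts, function(v) mean(stat_basis(v)), numeric(1)))
    sdev <- unname(vapply(counts, function(v) sd_basis(stat_basis(v)), numeric(1)))
  }

  removed <- list()
  degenerate <- is.na(sdev) | sdev == 0
  if (any(degenerate))
    warning("count standard deviation is zero; no positions removed on ",
            paste(names(counts)[degenerate], collapse = "/"), " strand",
            call. = FALSE)
  for (s in 1:2) {
    v <- counts[[s]]
    if (degenerate[s]) {
      removed[[s]] <- data.frame(position = integer(0), strand = character(0),
                                 count = numeric(0), z = numeric(0))
      next
    }
    z <- (v - mu[s]) / sdev[s]
    bad <- which(v >= 1 & z > z_threshold)
    removed[[s]] <- data.frame(position = bad - 1L,
                               strand = rep(names(counts)[s], length(bad)),
                               count = v[bad], z = z[bad])
    counts[[s]][bad] <- 0
  }
  removed <- rbind(removed[[1L]], removed[[2L]])
  out <- tag_set(counts$`+`, counts$`-`, tags$genome_length,
                 circular = tags$circular, tag_length = tags$tag_length)
  report <- structure(list(
    z_threshold = z_threshold,
    removed_positions = removed[order(removed$position), , drop = FALSE],
    tags_removed = sum(removed$count),
    mean = mu, sd = sdev,
    pool_strands = pool_strands, include_zeros = include_zeros
  ), class = "qc_report")
  list(tags = out, report = report)
}

sd_basis <- function(v) {
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: Z > %g filter removed %d positions (%s tags)\n",
              x$z_threshold, nrow(x$removed_positions),
              format(x$tags_removed, big.mark = ",")))
  cat(sprintf("  occupied-position count mean: %s; sd: %s\n",
              paste(sprintf("%.3f", x$mean), collapse = "/"),
              paste(sprintf("%.3f", x$sd), collapse = "/")))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [filter_anomalous_positions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$removed_positions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts GFF3 (records with type `gene`, or all records if none are typed
#' `gene`) or BED6. The TSS is the strand-aware 5' gene boundary and the TES
#' the 3' boundary, both 0-based, so minus-strand genes have `tss > tes` in
#' genome coordinates. Records without a strand are skipped with a warning.
#'
#' @param path path to a GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return a data.frame with columns `name`, `tss`, `tes`, `strand`,
#'   `start`, `end` (0-based half-open gene body).
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else if (ext == "bed") "bed" else
      stop(sprintf("cannot infer annotation format from extension '.%s'", ext), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED")
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  str <- as.character(GenomicRanges::strand(gr))
  if (any(str == "*")) {
    warning(sprintf("%d annotation records lack a strand and were skipped",
                    sum(str == "*")), call. = FALSE)
    gr <- gr[str != "*"]
    str <- str[str != "*"]
  }
  nm <- NULL
  mc <- S4Vectors::mcols(gr)
  for (col in c("Name", "ID", "name")) {
    if (col %in% names(mc)) { nm <- as.character(mc[[col]]); break }
  }
  if (is.null(nm)) nm <- sprintf("gene%05d", seq_along(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr) # half-open
  data.frame(
    name = nm,
    tss = ifelse(str == "+", start0, end0 - 1L),
    tes = ifelse(str == "+", end0 - 1L, start0),
    strand = str,
    start = start0,
    end = end0,
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations as GFF3
#' @param genes a data.frame as returned by [read_annotations()].
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path, chrom = "chr") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = genes$start + 1L, end = genes$end),
                               strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$name
  S4Vectors::mcols(gr)$Name <- genes$name
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a per-position numeric track as bedGraph
#'
#' Consecutive equal values are collapsed into single intervals.
#'
#' @param values numeric vector, one value per genome position.
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path, chrom = "chr") {
  r <- rle(values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track into a per-position vector
#'
#' Binned intervals are expanded to per-bp resolution by constant fill;
#' positions not covered by any interval are zero.
#'
#' @param path bedGraph path.
#' @param genome_length genome size in bp.
#' @return numeric vector of length `genome_length`.
#' @export
read_bedgraph <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- numeric(genome_length)
  s <- GenomicRanges::start(gr)
  e <- pmin(GenomicRanges::end(gr), genome_length)
  v <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) values[s[i]:e[i]] <- v[i]
  values
}
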