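# Synthetic-data generator: genomes with planted A-tracts, gene annotations,
# and nucleoid/control digestion-tag sets with known ground truth.
#
# Every generator is a pure function of (config, seed). A single global seed
# feeds a fixed per-stage substream scheme (see stage_seed): stage 1 places
# footprint clusters, 2 places genes, 3 draws the background sequence,
# 4 plants A-tracts, 5 samples nucleoid fragments, 6 samples control
# fragments, 7/8 inject anomalies into the nucleoid/control tag sets.

#' Generate a synthetic genome with planted structure
#'
#' Draws an i.i.d. background sequence at the configured GC content, places
#' footprint clusters (groups of 2-5 protected footprints whose centers are
#' spaced by the configured period) and non-overlapping genes, then plants
#' A-tracts (runs of A followed by runs of T, total length 3-10 bp) at loop
#' apexes - the gaps between successive footprints of a cluster - and, at
#' three times that rate, in the promoter window of each gene. Planted
#' tracts are flanked by forced non-A/T bases so that they are maximal and
#' are recovered exactly by [find_atracts()].
#'
#' @param config a [sim_config()].
#' @return a list with elements `sequence` (a single character string) and
#'   `truth`, the ground-truth record: data.frames `footprints` (`start`,
#'   `end`, `cluster`), `clusters` (`start`, `end`, `n_footprints`), `genes`
#'   (`name`, `tss`, `tes`, `strand`, `start`, `end`), `planted_atracts`
#'   (`start`, `end`, `nA`, `nT`), and `seed_used`. All intervals are
#'   0-based half-open.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  G <- config$genome_length

  # --- stage 1: footprint clusters ------------------------------------------
  set.seed(stage_seed(config$seed, 1L))
  kmin <- config$footprints_per_cluster[1]
  kmax <- config$footprints_per_cluster[2]
  period <- config$footprint_spacing_period
  flen <- config$footprint_length
  n_clusters <- stats::rpois(1L, config$cluster_rate * G / 1000)
  min_gap <- period # keeps neighbouring clusters resolvable
  footprints <- data.frame(start = integer(0), end = integer(0), cluster = integer(0))
  clusters <- data.frame(start = integer(0), end = integer(0), n_footprints = integer(0))
  if (n_clusters > 0) {
    k <- sample(seq.int(kmin, kmax), n_clusters, replace = TRUE)
    span <- (k - 1L) * period + flen
    # drop clusters (from the end) until spans + minimal gaps fit the genome
    while (n_clusters > 0 && sum(span) + n_clusters * min_gap >= G) {
      n_clusters <- n_clusters - 1L
      k <- k[seq_len(n_clusters)]
      span <- span[seq_len(n_clusters)]
    }
    if (n_clusters > 0) {
      free <- G - sum(span) - n_clusters * min_gap
      cuts <- sort(stats::runif(n_clusters, 0, free))
      gaps <- diff(c(0, cuts)) + min_gap
      starts <- floor(cumsum(gaps) + c(0, cumsum(span))[seq_len(n_clusters)])
      fp_start <- unlist(lapply(seq_len(n_clusters), function(i)
        starts[i] + (seq_len(k[i]) - 1L) * period))
      footprints <- data.frame(
        start = as.integer(fp_start),
        end = as.integer(fp_start + flen),
        cluster = rep.int(seq_len(n_clusters), k)
      )
      clusters <- data.frame(
        start = as.integer(starts),
        end = as.integer(starts + span),
        n_footprints = as.integer(k)
      )
    }
  }

  # --- stage 2: genes --------------------------------------------------------
  set.seed(stage_seed(config$seed, 2L))
  genes <- data.frame(name = character(0), tss = integer(0), tes = integer(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (config$n_genes > 0) {
    ng <- config$n_genes
    glen <- sample(seq.int(config$gene_length_range[1], config$gene_length_range[2]),
                   ng, replace = TRUE)
    if (sum(glen) + ng >= G)
      stop_config("n_genes", "does not fit the genome at the configured gene lengths")
    free <- G - sum(glen) - ng
    cuts <- sort(stats::runif(ng, 0, free))
    gaps <- diff(c(0, cuts)) + 1
    gstart <- floor(cumsum(gaps) + c(0, cumsum(glen))[seq_len(ng)])
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    genes <- data.frame(
      name = sprintf("gene%04d", seq_len(ng)),
      tss = as.integer(ifelse(gstrand == "+", gstart, gstart + glen - 1L)),
      tes = as.integer(ifelse(gstrand == "+", gstart + glen - 1L, gstart)),
      strand = gstrand,
      start = as.integer(gstart),
      end = as.integer(gstart + glen),
      stringsAsFactors = FALSE
    )
  }

  # --- stage 3: background sequence -----------------------------------------
  set.seed(stage_seed(config$seed, 3L))
  p_gc <- config$gc_content / 2
  p_at <- (1 - config$gc_content) / 2
  seqv <- sample(c("A", "C", "G", "T"), G, replace = TRUE,
                 prob = c(p_at, p_gc, p_gc, p_at))

  # --- stage 4: planted A-tracts --------------------------------------------
  set.seed(stage_seed(config$seed, 4L))
  proposals <- list()
  rate <- config$atract_cluster_rate
  if (rate > 0 && nrow(footprints) > 1) {
    # loop apexes: gaps between successive footprints within a cluster
    same <- footprints$cluster[-1] == footprints$cluster[-nrow(footprints)]
    gap_lo <- footprints$end[-nrow(footprints)][same]
    gap_hi <- footprints$start[-1][same]
    n_t <- stats::rpois(length(gap_lo), rate)
    idx <- rep.int(seq_along(gap_lo), n_t)
    if (length(idx) > 0)
      proposals[[1L]] <- propose_tracts(gap_lo[idx] + 1L, gap_hi[idx] - 1L)
  }
  if (rate > 0 && nrow(genes) > 0) {
    # promoter windows, oriented along transcription
    pw <- config$promoter_window
    w_lo <- ifelse(genes$strand == "+", genes$tss + pw[1], genes$tss - pw[2] + 1L)
    w_hi <- ifelse(genes$strand == "+", genes$tss + pw[2], genes$tss - pw[1] + 1L)
    n_t <- stats::rpois(nrow(genes), 3 * rate)
    idx <- rep.int(seq_len(nrow(genes)), n_t)
    if (length(idx) > 0)
      proposals[[2L]] <- propose_tracts(pmax(w_lo[idx], 1L), pmin(w_hi[idx], G - 12L))
  }
  planted <- resolve_tract_proposals(proposals)
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      s <- planted$start[i] # 0-based tract start
      nA <- planted$nA[i]
      nT <- planted$nT[i]
      if (nA > 0) seqv[(s + 1L):(s + nA)] <- "A"
      if (nT > 0) seqv[(s + nA + 1L):(s + nA + nT)] <- "T"
      # force maximality: flanking bases are never A/T
      seqv[s] <- sample(c("C", "G"), 1L)
      seqv[s + nA + nT + 1L] <- sample(c("C", "G"), 1L)
    }
  }

  truth <- structure(list(
    footprints = footprints,
    clusters = clusters,
    genes = genes,
    planted_atracts = planted,
    seed_used = config$seed
  ), class = "ground_truth")
  list(sequence = paste(seqv, collapse = ""), truth = truth)
}

# Draw tract composition for windows [lo, hi] (1-based inclusive bounds of
# admissible tract bases). Returns 0-based tract starts with components.
propose_tracts <- function(lo, hi) {
  len <- sample(3:10, length(lo), replace = TRUE)
  nA <- floor(stats::runif(length(lo)) * (len + 1L)) # uniform on 0..len
  ok <- hi - lo + 1L >= len
  lo <- lo[ok]; hi <- hi[ok]; len <- len[ok]; nA <- nA[ok]
  if (length(lo) == 0)
    return(data.frame(start = integer(0), end = integer(0), nA = integer(0), nT = integer(0)))
  start1 <- lo + floor(stats::runif(length(lo)) * (hi - lo - len + 2L))
  data.frame(start = as.integer(start1 - 1L), end = as.integer(start1 - 1L + len),
             nA = as.integer(nA), nT = as.integer(len - nA))
}

# Greedy overlap resolution on flank-inclusive intervals [start-1, end+1).
resolve_tract_proposals <- function(proposals) {
  df <- do.call(rbind, proposals)
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(start = integer(0), end = integer(0), nA = integer(0), nT = integer(0)))
  df <- df[order(df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  last_end <- -2L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] - 1L > last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i] # flank position df$end[i] is occupied
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d footprints in %d clusters, %d genes, %d planted A-tracts (seed %s)\n",
              nrow(x$footprints), nrow(x$clusters), nrow(x$genes),
              nrow(x$planted_atracts), format(x$seed_used)))
  invisible(x)
}

#' Sample nucleoid digestion tags from planted footprints
#'
#' Each sampled fragment is a footprint with Gaussian-jittered boundaries;
#' the fragment always yields a plus-strand tag at its left end and, with
#' probability `paired_end_prob`, a minus-strand tag whose 5'-end is the
#' fragment's rightmost base. Fragments whose center falls within
#' `tss_depletion_halfwidth` of any TSS or TES are rejected with probability
#' `tss_depletion_depth`, carving the accessibility dips seen at gene
#' boundaries. Sampling stops when exactly `n_nucleoid_tags` tags have been
#' emitted.
#'
#' @param sequence genome sequence (string); only its length is used here.
#' @param truth ground truth from [generate_genome()].
#' @param config a [sim_config()].
#' @return a [tag_set()]; the sampled fragments (columns `left`, `right`,
#'   `paired`) are attached as attribute `"fragments"` for QC use.
#' @export
generate_nucleoid_tags <- function(sequence, truth, config) {
  validate_sim_config(config)
  G <- config$genome_length
  if (nchar(sequence[1L]) != G && length(sequence) != G)
    stop("'truth'/'sequence' inconsistent with config genome_length", call. = FALSE)
  fp <- truth$footprints
  if (is.null(fp) || nrow(fp) == 0)
    stop("no footprints to sample from", call. = FALSE)

  # per-position acceptance factor encoding TSS/TES depletion
  f <- rep(1, G)
  if (nrow(truth$genes) > 0 && config$tss_depletion_depth > 0) {
    hw <- config$tss_depletion_halfwidth
    sites <- c(truth$genes$tss, truth$genes$tes)
    win <- as.vector(outer(-hw:hw, sites, `+`)) %% G
    f[win + 1L] <- 1 - config$tss_depletion_depth
  }

  set.seed(stage_seed(config$seed, 5L))
  need <- config$n_nucleoid_tags
  p <- config$paired_end_prob
  jit <- config$boundary_jitter_sd
  frag_l <- integer(0); frag_r <- integer(0); frag_p <- logical(0)
  emitted <- 0
  while (emitted < need) {
    m <- ceiling((need - emitted) / (1 + p) * 1.4) + 50L
    fi <- sample.int(nrow(fp), m, replace = TRUE)
    l <- fp$start[fi] + round(stats::rnorm(m, 0, jit))
    r <- fp$end[fi] - 1L + round(stats::rnorm(m, 0, jit))
    ok <- l >= 0 & r < G & r > l
    l <- l[ok]; r <- r[ok]
    ctr <- (l + r) %/% 2L
    acc <- stats::runif(length(l)) < f[ctr + 1L]
    l <- l[acc]; r <- r[acc]
    pr <- stats::runif(length(l)) < p
    frag_l <- c(frag_l, l); frag_r <- c(frag_r, r); frag_p <- c(frag_p, pr)
    emitted <- emitted + length(l) + sum(pr)
  }
  trimmed <- trim_to_tag_count(frag_l, frag_r, frag_p, need)
  build_tag_set_from_fragments(trimmed, G, config)
}

#' Sample control tags from unconstrained digestion of naked DNA
#'
#' Fragments are placed uniformly on the genome (optionally with an A/T
#' cut-site bias at the fragment start) with lengths uniform on
#' `control_fragment_length_range`; tag emission follows the same paired-end
#' scheme as the nucleoid sample. The resulting tag set has no
#' characteristic fragment length and no spacing periodicity.
#'
#' @param sequence genome sequence (string), used for the A/T cut bias.
#' @param config a [sim_config()].
#' @return a [tag_set()] with sampled fragments attached as attribute
#'   `"fragments"`.
#' @export
generate_control_tags <- function(sequence, config) {
  validate_sim_config(config)
  G <- config$genome_length
  seqv <- as_base_vector(sequence)
  if (length(seqv) != G)
    stop("'sequence' length does not match config genome_length", call. = FALSE)
  w <- ifelse(seqv %in% c("A", "T"), config$at_bias, 1)
  cw <- cumsum(w)
  total <- cw[G]

  set.seed(stage_seed(config$seed, 6L))
  need <- config$n_control_tags
  p <- config$paired_end_prob
  lmin <- config$control_fragment_length_range[1]
  lmax <- config$control_fragment_length_range[2]
  frag_l <- integer(0); frag_r <- integer(0); frag_p <- logical(0)
  emitted <- 0
  while (emitted < need) {
    m <- ceiling((need - emitted) / (1 + p) * 1.2) + 50L
    l <- findInterval(stats::runif(m) * total, cw) # 0-based start positions
    len <- lmin + floor(stats::runif(m) * (lmax - lmin + 1L))
    r <- l + len - 1L
    if (config$circular) {
      r <- r %% G
    } else {
      keep <- r < G
      l <- l[keep]; r <- r[keep]
    }
    pr <- stats::runif(length(l)) < p
    frag_l <- c(frag_l, l); frag_r <- c(frag_r, r); frag_p <- c(frag_p, pr)
    emitted <- emitted + length(l) + sum(pr)
  }
  trimmed <- trim_to_tag_count(frag_l, frag_r, frag_p, need)
  build_tag_set_from_fragments(trimmed, G, config)
}

# Keep fragments until exactly n tags are emitted; if the cut lands inside a
# pair, the trailing minus tag is dropped.
trim_to_tag_count <- function(l, r, paired, n) {
  tags_per_frag <- 1L + as.integer(paired)
  cum <- cumsum(tags_per_frag)
  k <- findInterval(n, cum)
  if (k > 0 && cum[k] == n) {
    idx <- seq_len(k)
    return(data.frame(left = l[idx], right = r[idx], paired = paired[idx]))
  }
  idx <- seq_len(k + 1L)
  out <- data.frame(left = l[idx], right = r[idx], paired = paired[idx])
  out$paired[k + 1L] <- FALSE # keep only the plus tag of the boundary fragment
  out
}

build_tag_set_from_fragments <- function(frags, G, config) {
  cp <- tabulate(frags$left + 1L, nbins = G)
  cm <- tabulate(frags$right[frags$paired] + 1L, nbins = G)
  out <- tag_set(cp, cm, G, circular = config$circular, tag_length = config$tag_length)
  attr(out, "fragments") <- frags
  out
}

#' Inject amplification-artifact pile-ups into a tag set
#'
#' Emulates the PCR-duplication artifact class removed by the Z-score filter:
#' a small random set of positions per strand has its count inflated to at
#' least fifty times the mean count of occupied positions on that strand.
#' Injected positions are recorded in attribute `"injected"` so QC tests can
#' verify their removal.
#'
#' @param tags a [tag_set()].
#' @param config a [sim_config()]; `anomaly_spike_rate` gives the expected
#'   fraction of positions spiked per strand.
#' @param stage substream index for the random draws (default distinguishes
#'   nucleoid from control injection).
#' @return a [tag_set()] with inflated counts.
#' @export
inject_anomalies <- function(tags, config, stage = 7L) {
  stopifnot(inherits(tags, "tag_set"))
  validate_sim_config(config)
  rate <- config$anomaly_spike_rate
  G <- tags$genome_length
  injected <- data.frame(position = integer(0), strand = character(0), count = numeric(0))
  if (rate == 0) {
    attr(tags, "injected") <- injected
    return(tags)
  }
  set.seed(stage_seed(config$seed, stage))
  counts <- list(`+` = tags$counts_plus, `-` = tags$counts_minus)
  for (s in c("+", "-")) {
    n_spk <- stats::rbinom(1L, G, rate)
    if (n_spk == 0) next
    pos <- sample.int(G, n_spk) - 1L
    nz <- counts[[s]][counts[[s]] >= 1]
    target <- ceiling(50 * if (length(nz)) mean(nz) else 1)
    counts[[s]][pos + 1L] <- pmax(counts[[s]][pos + 1L], target)
    injected <- rbind(injected, data.frame(position = pos, strand = s,
                                           count = counts[[s]][pos + 1L]))
  }
  out <- tag_set(counts$`+`, counts$`-`, G, circular = tags$circular,
                 tag_length = tags$tag_length)
  attr(out, "fragments") <- attr(tags, "fragments")
  attr(out, "injected") <- injected[order(injected$position), , drop = FALSE]
  out
}

#' Simulate a complete study data set
#'
#' Runs the full generator chain - genome, annotations, nucleoid tags,
#' control tags, anomaly injection - and optionally writes everything to
#' disk in standard formats: `genome.fa` (FASTA), `genes.gff3`/`genes.bed`,
#' `nucleoid.bed`/`control.bed` (BED6 tag sets) and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return a list with `sequence`, `truth`, `nucleoid` and `control`
#'   (tag sets, with anomalies injected at the configured rate), and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  gen <- generate_genome(config)
  nucleoid <- generate_nucleoid_tags(gen$sequence, gen$truth, config)
  control <- generate_control_tags(gen$sequence, config)
  nucleoid <- inject_anomalies(nucleoid, config, stage = 7L)
  control <- inject_anomalies(control, config, stage = 8L)
  out <- list(sequence = gen$sequence, truth = gen$truth,
              nucleoid = nucleoid, control = control, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    dna <- Biostrings::DNAStringSet(gen$sequence)
    names(dna) <- "chr"
    Biostrings::writeXStringSet(dna, file.path(outdir, "genome.fa"))
    if (nrow(gen$truth$genes) > 0) {
      write_annotations(gen$truth$genes, file.path(outdir, "genes.gff3"))
      bed <- GenomicRanges::GRanges("chr",
        IRanges::IRanges(start = gen$truth$genes$start + 1L, end = gen$truth$genes$end),
        strand = gen$truth$genes$strand)
      bed$name <- gen$truth$genes$name
      bed$score <- 0
      rtracklayer::export(bed, file.path(outdir, "genes.bed"), format = "BED")
    }
    write_tags(nucleoid, file.path(outdir, "nucleoid.bed"))
    write_tags(control, file.path(outdir, "control.bed"))
    jsonlite::write_json(unclass(gen$truth), file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  out
}
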