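#' Simulation configuration for the synthetic nucleoid-digestion generator
#'
#' Bundles every tunable of the synthetic-data module with defaults that
#' mirror the study conditions the analysis is designed around: 50-bp
#' protected footprints spaced with a 93-bp period in small clusters on a
#' circular genome, 36-bp 5'-end tags, accessibility dips at gene starts and
#' ends, and a naked-DNA control digested without positional constraint.
#'
#' @param genome_length genome size in bp.
#' @param circular logical; positions wrap modulo `genome_length` when `TRUE`.
#' @param gc_content genome GC fraction for the i.i.d. background sequence.
#' @param n_genes number of non-overlapping genes to place.
#' @param footprint_length length in bp of a protected (digestion-resistant)
#'   footprint.
#' @param footprint_spacing_period center-to-center distance in bp between
#'   successive footprints within a cluster.
#' @param footprints_per_cluster integer range `c(min, max)`; the number of
#'   footprints per cluster is drawn uniformly from it.
#' @param cluster_rate expected clusters per kb of genome.
#' @param tss_depletion_halfwidth half-width in bp of the accessibility window
#'   around each TSS and TES.
#' @param tss_depletion_depth fraction of baseline fragment density removed
#'   inside the depletion window (1 = complete depletion).
#' @param atract_cluster_rate expected planted A-tracts per loop apex (the
#'   gap between successive footprints of a cluster). Promoter windows
#'   receive three times this rate.
#' @param tag_length sequenced tag length in bp (tags are fragment
#'   5'-prefixes, so `tag_length <= footprint_length`).
#' @param n_nucleoid_tags total tags emitted for the nucleoid sample.
#' @param n_control_tags total tags emitted for the control sample.
#' @param control_fragment_length_range `c(min, max)` bp; control fragment
#'   lengths are uniform on this range.
#' @param at_bias multiplicative cut-rate preference for A/T positions in the
#'   control digestion (1 = no sequence bias).
#' @param boundary_jitter_sd standard deviation in bp of the Gaussian jitter
#'   applied to each sampled fragment boundary.
#' @param paired_end_prob probability that a sampled fragment yields a
#'   minus-strand tag at its right end in addition to the plus-strand tag at
#'   its left end.
#' @param anomaly_spike_rate fraction of genome positions (per strand) given
#'   amplification-artifact pile-ups by [inject_anomalies()].
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed) via a fixed per-stage substream scheme.
#' @param gene_length_range `c(min, max)` bp for simulated gene lengths.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS, in
#'   transcription direction, receiving elevated A-tract planting.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_genome()], [generate_nucleoid_tags()],
#'   [generate_control_tags()], [simulate_dataset()]
#' @export
sim_config <- function(genome_length = 1e6,
                       circular = TRUE,
                       gc_content = 0.51,
                       n_genes = 500,
                       footprint_length = 50,
                       footprint_spacing_period = 93,
                       footprints_per_cluster = c(2, 5),
                       cluster_rate = 0.5,
                       tss_depletion_halfwidth = 50,
                       tss_depletion_depth = 0.6,
                       atract_cluster_rate = 1,
                       tag_length = 36,
                       n_nucleoid_tags = 200000,
                       n_control_tags = 200000,
                       control_fragment_length_range = c(50, 500),
                       at_bias = 1.5,
                       boundary_jitter_sd = 3,
                       paired_end_prob = 0.5,
                       anomaly_spike_rate = 1e-5,
                       seed = 1,
                       gene_length_range = c(600, 1800),
                       promoter_window = c(-100, 20)) {
  cfg <- list(
    genome_length = genome_length, circular = circular,
    gc_content = gc_content, n_genes = n_genes,
    footprint_length = footprint_length,
    footprint_spacing_period = footprint_spacing_period,
    footprints_per_cluster = footprints_per_cluster,
    cluster_rate = cluster_rate,
    tss_depletion_halfwidth = tss_depletion_halfwidth,
    tss_depletion_depth = tss_depletion_depth,
    atract_cluster_rate = atract_cluster_rate,
    tag_length = tag_length,
    n_nucleoid_tags = n_nucleoid_tags,
    n_control_tags = n_control_tags,
    control_fragment_length_range = control_fragment_length_range,
    at_bias = at_bias,
    boundary_jitter_sd = boundary_jitter_sd,
    paired_end_prob = paired_end_prob,
    anomaly_spike_rate = anomaly_spike_rate,
    seed = seed,
    gene_length_range = gene_length_range,
    promoter_window = promoter_window
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$genome_length)) stop_config("genome_length", "must be a positive integer")
  if (!is.logical(cfg$circular) || length(cfg$circular) != 1L || is.na(cfg$circular))
    stop_config("circular", "must be TRUE or FALSE")
  if (!is_fraction(cfg$gc_content)) stop_config("gc_content", "must be in [0, 1]")
  if (!(is_count(cfg$n_genes) || identical(as.numeric(cfg$n_genes), 0)))
    stop_config("n_genes", "must be a non-negative integer")
  if (!is_count(cfg$footprint_length)) stop_config("footprint_length", "must be a positive integer")
  if (!is_count(cfg$footprint_spacing_period))
    stop_config("footprint_spacing_period", "must be a positive integer")
  if (cfg$footprint_length >= cfg$footprint_spacing_period)
    stop_config("footprint_length", "must be smaller than footprint_spacing_period")
  fpc <- cfg$footprints_per_cluster
  if (length(fpc) != 2L || !is_count(fpc[1]) || !is_count(fpc[2]) || fpc[1] > fpc[2])
    stop_config("footprints_per_cluster", "must be an increasing positive integer pair")
  if (!is.numeric(cfg$cluster_rate) || cfg$cluster_rate < 0)
    stop_config("cluster_rate", "must be non-negative")
  if (!is_count(cfg$tss_depletion_halfwidth))
    stop_config("tss_depletion_halfwidth", "must be a positive integer")
  if (!is_fraction(cfg$tss_depletion_depth))
    stop_config("tss_depletion_depth", "must be in [0, 1]")
  if (!is.numeric(cfg$atract_cluster_rate) || cfg$atract_cluster_rate < 0)
    stop_config("atract_cluster_rate", "must be non-negative")
  if (!is_count(cfg$tag_length)) stop_config("tag_length", "must be a positive integer")
  if (cfg$tag_length > cfg$footprint_length)
    stop_config("tag_length", "must not exceed footprint_length (tags are fragment 5'-prefixes)")
  if (!is_count(cfg$n_nucleoid_tags)) stop_config("n_nucleoid_tags", "must be a positive integer")
  if (!is_count(cfg$n_control_tags)) stop_config("n_control_tags", "must be a positive integer")
  cflr <- cfg$control_fragment_length_range
  if (length(cflr) != 2L || !is_count(cflr[1]) || !is_count(cflr[2]) || cflr[1] > cflr[2])
    stop_config("control_fragment_length_range", "must be an increasing positive integer pair")
  if (!is.numeric(cfg$at_bias) || length(cfg$at_bias) != 1L || cfg$at_bias <= 0)
    stop_config("at_bias", "must be a positive number")
  if (!is.numeric(cfg$boundary_jitter_sd) || cfg$boundary_jitter_sd < 0)
    stop_config("boundary_jitter_sd", "must be non-negative")
  if (!is_fraction(cfg$paired_end_prob)) stop_config("paired_end_prob", "must be in [0, 1]")
  if (!is_fraction(cfg$anomaly_spike_rate)) stop_config("anomaly_spike_rate", "must be in [0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")
  glr <- cfg$gene_length_range
  if (length(glr) != 2L || !is_count(glr[1]) || !is_count(glr[2]) || glr[1] > glr[2])
    stop_config("gene_length_range", "must be an increasing positive integer pair")
  if (length(cfg$promoter_window) != 2L || cfg$promoter_window[1] > cfg$promoter_window[2])
    stop_config("promoter_window", "must be an increasing pair of offsets")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic nucleoid-digestion configuration\n")
  cat(sprintf("  genome: %s bp (%s), GC %.2f, %d genes\n",
              format(x$genome_length, big.mark = ","),
              if (x$circular) "circular" else "linear", x$gc_content, x$n_genes))
  cat(sprintf("  footprints: %d bp, period %d bp, %d-%d per cluster, %.2f clusters/kb\n",
              x$footprint_length, x$footprint_spacing_period,
              x$footprints_per_cluster[1], x$footprints_per_cluster[2], x$cluster_rate))
  cat(sprintf("  tags: %d bp; nucleoid %s, control %s; paired-end prob %.2f\n",
              x$tag_length, format(x$n_nucleoid_tags, big.mark = ","),
              format(x$n_control_tags, big.mark = ","), x$paired_end_prob))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}
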