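# End-to-end orchestration: tags -> QC -> fragment size -> periodicity ->
# centers -> profiles -> cluster calling -> sequence statistics -> report.

#' Build a pipeline run configuration
#'
#' Collects input paths and every stage parameter, with defaults matching
#' the analysis constants used throughout the package: Z-score 7 anomaly
#' filter, 25-bp correlation smoothing, 25-bp KDE bandwidth, FDR 10^-3 with
#' 20 randomizations, 25-bp minimum cluster length and merge gap, 50-bp
#' profile smoothing, tract lengths 3-10 with 15 shuffled genomes.
#'
#' @param tags path to the nucleoid tag file (BED6/SAM/BAM).
#' @param genome_length genome size in bp (required when no FASTA is given).
#' @param control_tags optional path to the control tag file.
#' @param fasta optional genome FASTA (single record).
#' @param annotations optional GFF3/BED gene annotations.
#' @param chip_track optional bedGraph of an external ChIP signal.
#' @param outdir output directory.
#' @param circular logical; genome circularity.
#' @param z_threshold anomalous-position Z-score threshold.
#' @param read_length sequenced tag length in bp.
#' @param max_lag_cross,max_lag_auto correlation lag ranges in bp.
#' @param correlation_window correlation smoothing window in bp.
#' @param period_range period search range in bp.
#' @param bandwidth KDE bandwidth in bp.
#' @param fdr cluster-calling FDR target.
#' @param n_rand_fdr randomizations for FDR calibration.
#' @param min_length,merge_gap cluster length/merge parameters in bp.
#' @param min_ratio control-enrichment filter threshold.
#' @param flank,profile_window metagene flank and smoothing window in bp.
#' @param tract_bounds `c(min, max)` A-tract length bounds in bp.
#' @param n_rand_tracts shuffled genomes for the genome-to-random ratio.
#' @param chip_flank flank for the ChIP profile around cluster centers.
#' @param fallback_fragment_size fragment size used for center shifting when
#'   no cross-correlation estimate exists (control-like input).
#' @param seed global seed for all randomized stages.
#' @return a `run_config` list.
#' @export
run_config <- function(tags, genome_length = NULL, control_tags = NULL,
                       fasta = NULL, annotations = NULL, chip_track = NULL,
                       outdir = "nucfoot_out", circular = TRUE,
                       z_threshold = 7, read_length = 36,
                       max_lag_cross = 500, max_lag_auto = 1000,
                       correlation_window = 25, period_range = c(50, 500),
                       bandwidth = 25, fdr = 1e-3, n_rand_fdr = 20,
                       min_length = 25, merge_gap = 25, min_ratio = 1.0,
                       flank = 500, profile_window = 50,
                       tract_bounds = c(3, 10), n_rand_tracts = 15,
                       chip_flank = 1000, fallback_fragment_size = 50,
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Executes, in order: tag reading and the anomalous-position filter; strand
#' cross-correlation and fragment-size estimation; strand auto-correlation
#' and Fourier periodicity; fragment-center conversion; TSS/TES metagene,
#' GC and A-tract profiles (when annotations and FASTA are given); KDE
#' cluster calling with FDR calibration and control filtering (when control
#' tags are given); A-tract spectra and genome-to-random ratios; and the
#' ChIP profile around cluster centers (when a track is given). Every stage
#' writes its outputs under `config$outdir`, and a JSON + Markdown report
#' summarizes the headline quantities. A missing fragment-size peak
#' (control-like input) is recorded as `fragment_size = NA` with flag
#' `no_fragment_size_estimate`; center shifting then falls back to
#' `config$fallback_fragment_size` so the pipeline completes.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (also written to `report.json` and
#'   `report.md`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[!vapply(config, is.null, logical(1))])
  out <- function(...) file.path(config$outdir, ...)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "nucfoot_no_estimate")) stop(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sequence <- NULL
  if (!is.null(config$fasta)) {
    dna <- run_stage("fasta", Biostrings::readDNAStringSet(config$fasta))
    if (length(dna) != 1L)
      stop("pipeline stage 'fasta' failed: expected a single-record FASTA", call. = FALSE)
    sequence <- as.character(dna[[1L]])
    config$genome_length <- nchar(sequence)
  }
  if (is.null(config$genome_length))
    stop("genome_length is required when no FASTA is given", call. = FALSE)
  G <- config$genome_length

  # --- QC ---------------------------------------------------------------
  tags <- run_stage("qc", {
    raw <- read_tags(config$tags, G, circular = config$circular,
                     tag_length = config$read_length)
    qc <- filter_anomalous_positions(raw, z_threshold = config$z_threshold)
    write_qc_report(qc$report, out("qc_removed_positions.tsv"))
    report$qc <- list(n_tags_in = raw$n_tags,
                      n_tags_removed = qc$report$tags_removed,
                      n_positions_removed = nrow(qc$report$removed_positions))
    qc$tags
  })
  control <- NULL
  if (!is.null(config$control_tags)) {
    control <- run_stage("qc_control", {
      raw <- read_tags(config$control_tags, G, circular = config$circular,
                       tag_length = config$read_length)
      filter_anomalous_positions(raw, z_threshold = config$z_threshold)$tags
    })
  }

  # --- fragment size ----------------------------------------------------
  cc <- run_stage("fragsize", strand_cross_correlation(
    tags, max_lag = config$max_lag_cross, window = config$correlation_window))
  write_correlation_profile(cc, out("cross_correlation.tsv"))
  est <- tryCatch(
    estimate_fragment_size(cc, read_length = config$read_length),
    nucfoot_no_estimate = function(e) NULL)
  report$no_fragment_size_estimate <- is.null(est)
  report$fragment_size <- if (is.null(est)) NA else est$fragment_size
  report$technical_peak_lag <- if (is.null(est)) NA else est$technical_peak_lag

  # --- periodicity ------------------------------------------------------
  ac <- run_stage("periodicity", strand_auto_correlation(
    tags, max_lag = config$max_lag_auto, window = config$correlation_window))
  write_correlation_profile(ac, out("auto_correlation.tsv"))
  pg <- run_stage("periodicity", periodogram(ac, period_range = config$period_range))
  write_periodogram(pg, out("periodogram.tsv"))
  report$dominant_period <- pg$dominant_period

  # --- fragment centers -------------------------------------------------
  frag_size <- if (is.null(est)) config$fallback_fragment_size else est$fragment_size
  centers <- run_stage("centers", to_fragment_centers(tags, frag_size))
  write_bedgraph(centers$counts, out("fragment_centers.bedGraph"))

  # --- metagene profiles ------------------------------------------------
  genes <- NULL
  if (!is.null(config$annotations)) {
    genes <- run_stage("profiles", read_annotations(config$annotations))
    for (anchor in c("tss", "tes")) {
      mp <- run_stage("profiles", metagene_profile(
        centers, genes, anchor, flank = config$flank, window = config$profile_window))
      write_meta_profile(mp, out(sprintf("centers_%s_profile.tsv", anchor)))
      if (!is.null(sequence)) {
        gp <- run_stage("profiles", gc_metaprofile(
          sequence, genes, anchor, flank = config$flank,
          window = config$profile_window, circular = config$circular))
        write_meta_profile(gp, out(sprintf("gc_%s_profile.tsv", anchor)))
      }
    }
  }

  # --- cluster calling --------------------------------------------------
  clusters <- NULL
  dens <- run_stage("clusters", kde_density(centers, bandwidth = config$bandwidth))
  write_bedgraph(dens$values, out("nucleoid_density.bedGraph"))
  cal <- run_stage("clusters", calibrate_fdr_threshold(
    dens, fdr = config$fdr, n_rand = config$n_rand_fdr, seed = config$seed))
  jsonlite::write_json(list(density_threshold = cal$density_threshold,
                            fdr_target = cal$fdr_target,
                            n_randomizations = cal$n_randomizations,
                            seed = cal$seed),
                       out("fdr_calibration.json"), auto_unbox = TRUE, digits = NA)
  clusters <- run_stage("clusters", call_clusters(
    dens, cal$density_threshold,
    min_length = config$min_length, merge_gap = config$merge_gap))
  if (!is.null(control) && nrow(clusters) > 0) {
    ctl_centers <- run_stage("clusters", to_fragment_centers(control, frag_size))
    ctl_dens <- run_stage("clusters", kde_density(ctl_centers, bandwidth = config$bandwidth))
    clusters <- run_stage("clusters", filter_by_control(
      clusters, dens, ctl_dens, min_ratio = config$min_ratio))
    ratios <- attr(clusters, "ratios")
    utils::write.table(data.frame(enrichment_ratio = ratios),
                       out("cluster_enrichment_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_clusters_bed(clusters, out("clusters.bed"))
  report$n_clusters <- nrow(clusters)
  report$median_cluster_length <- if (nrow(clusters)) stats::median(clusters$end - clusters$start) else NA

  # --- sequence statistics ---------------------------------------------
  if (!is.null(sequence)) {
    tb <- config$tract_bounds
    tracts <- run_stage("atracts", find_atracts(sequence, tb[1], tb[2]))
    write_atracts_bed(tracts, out("atracts.bed"))
    spec_genome <- tract_frequency_spectrum(tracts, G, min_len = tb[1], max_len = tb[2])
    write_tract_stats(spec_genome, out("atract_spectrum_genome.tsv"))
    report$tract_frequency_per_kb <- stats::setNames(
      as.list(spec_genome$frequency_per_kb), paste0("L", spec_genome$lengths))
    if (!is.null(clusters) && nrow(clusters) > 0) {
      spec_cl <- tract_frequency_spectrum(tracts, G, regions = clusters,
                                          min_len = tb[1], max_len = tb[2])
      write_tract_stats(spec_cl, out("atract_spectrum_clusters.tsv"))
      report$cluster_gc <- gc_content(sequence, clusters)
    }
    ratio <- run_stage("atracts", genome_to_random_ratio(
      sequence, n_rand = config$n_rand_tracts, seed = config$seed,
      min_len = tb[1], max_len = tb[2]))
    write_tract_stats(ratio, out("atract_genome_to_random.tsv"))
    report$genome_to_random_ratio <- stats::setNames(
      as.list(ratio$genome_to_random_ratio), paste0("L", ratio$lengths))
    if (!is.null(genes)) {
      ap <- run_stage("atracts", atract_metaprofile(
        tracts, genes, G, flank = config$flank, circular = config$circular))
      write_meta_profile(ap, out("atract_tss_profile.tsv"))
    }
  }

  # --- ChIP association -------------------------------------------------
  if (!is.null(config$chip_track) && !is.null(clusters) && nrow(clusters) > 0) {
    chip <- run_stage("chip", {
      track <- zscore_track(read_bedgraph(config$chip_track, G))
      profile_around(cluster_centers(clusters, G), track,
                     flank = config$chip_flank, circular = config$circular)
    })
    write_meta_profile(chip, out("chip_cluster_profile.tsv"))
    report$chip_central_z <- chip$mean_value[chip$offsets == 0]
  }

  write_report(report, config$outdir)
  invisible(report)
}

write_report <- function(report, outdir) {
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", na = "null")
  md <- c(
    "# Nucleoid MNase footprinting report", "",
    sprintf("- tags after QC filter: %s",
            format(as.integer(report$qc$n_tags_in - report$qc$n_tags_removed),
                   big.mark = ",")),
    sprintf("- characteristic fragment size: %s bp%s",
            format(report$fragment_size),
            if (isTRUE(report$no_fragment_size_estimate))
              " (no estimate: control-like profile)" else ""),
    sprintf("- dominant spacing period: %.1f bp", report$dominant_period),
    sprintf("- clusters called: %s (median length %s bp)",
            format(report$n_clusters), format(report$median_cluster_length))
  )
  if (!is.null(report$cluster_gc))
    md <- c(md, sprintf("- cluster GC content: %.3f", report$cluster_gc))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(NULL)
}
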