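# nucfoot

In vivo MNase footprinting analysis of the bacterial nucleoid.

Bacterial chromosomes are compacted without nucleosomes, and one way to probe
how is to digest the nucleoid inside living cells with micrococcal nuclease
(MNase) and sequence what survives. `nucfoot` implements the complete
downstream analysis of such an experiment, starting from aligned 36-bp 5'-end
tags of digestion-resistant fragments:

- **Characteristic protected-fragment size** from strand cross-correlation:
  the Pearson correlation r(d) between plus- and minus-strand per-position
  tag counts as a function of shift d. Paired 5'-ends of one double-stranded
  fragment map to opposite strands one fragment length apart, so the
  non-technical maximum of r(d) estimates the protected length; the peak at
  the read length (35-36 bp), an alignment-uniqueness artifact, is excluded.
- **Spacing periodicity** from same-strand auto-correlation followed by a
  Fourier periodogram; the dominant period over 50-500 bp is the
  characteristic center-to-center distance between protected fragments.
- **Accessibility metagene profiles**: tags are shifted by half the fragment
  size to strandless fragment centers, then averaged in strand-oriented
  windows around all annotated TSS and TES, alongside matched GC-content and
  A-tract-frequency profiles.
- **Clusters of digestion-resistant fragments**: a Gaussian kernel density
  (bandwidth 25 bp) of fragment centers is thresholded at an empirical
  positionwise FDR of 10^-3 calibrated against uniform-placement
  randomizations; runs >= 25 bp are kept after merging gaps < 25 bp, and
  clusters not enriched over the naked-DNA control are removed.
- **A-tract statistics**: maximal AnTm runs (no internal TpA step,
  3 <= n+m <= 10) are enumerated; per-length frequency spectra are computed
  for arbitrary region sets, and the genome-to-random ratio
  r(L) = observed / mean count over 15 base-composition-preserving shuffles
  quantifies genomic excess.
- **ChIP association**: z-score-normalized external signal (e.g. H-NS
  binding) averaged around cluster centers.

A first-class synthetic-data generator produces circular genomes with
planted footprint clusters (50-bp footprints, 93-bp spacing), genes with
depleted-accessibility boundaries and A-tract-enriched promoters, and
matched nucleoid/control tag sets with full ground truth, so every estimator
is tested by parameter recovery.

## Worked example

```r
library(nucfoot)

cfg <- sim_config(seed = 1)            # 1-Mb circular genome, ~200k tags
sim <- simulate_dataset(cfg)

tags <- filter_anomalous_positions(sim$nucleoid, z_threshold = 7)$tags

cc  <- strand_cross_correlation(tags, max_lag = 500, window = 25)
est <- estimate_fragment_size(cc, read_length = 36)
est
#> fragment_size_estimate: 49 bp (smoothed cross-correlation peak 0.3507)

pg <- periodogram(strand_auto_correlation(tags, max_lag = 1000))
pg
#> periodogram: dominant period 95.2 bp in range 50-500 bp (1000 lags)

centers <- to_fragment_centers(tags, est$fragment_size)
dens    <- kde_density(centers, bandwidth = 25)
cal     <- calibrate_fdr_threshold(dens, fdr = 1e-3, n_rand = 20, seed = 20)
cl      <- call_clusters(dens, cal$density_threshold)
nrow(cl); median(cl$end - cl$start)
#> [1] 507
#> [1] 278
```

The 49-bp peak recovers the planted 50-bp footprint (paired 5'-ends of an
L-bp fragment sit L-1 apart); the dominant period recovers the planted 93-bp
spacing up to the Fourier grid; the ~500 clusters recover the planted
footprint clusters (about one per 2 kb), whose 2-5 periodic footprints merge
under the 25-bp kernel into calls a few hundred bp long.

`run_all(run_config(...))` chains every stage - QC, fragment size,
periodicity, centers, profiles, cluster calling with control filtering,
A-tract statistics, optional ChIP profile - and writes TSV/BED/bedGraph
outputs plus a JSON and Markdown report.

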