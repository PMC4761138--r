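---
title: "Methods: in vivo MNase footprinting analysis of a bacterial nucleoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vivo MNase footprinting analysis of a bacterial nucleoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement and its observables

Micrococcal nuclease expressed inside a living bacterium digests whatever
DNA it can reach; what survives is DNA occluded by proteins or by the
packing of the nucleoid itself. Sequencing the short digestion-resistant
fragments yields, after alignment, a set of *tags*: the 36-bp 5'-ends of
fragments, each assigned to a genome strand. `nucfoot` works entirely from
the per-strand, per-position counts of these tag 5'-ends (`tag_set`), on a
single circular chromosome.

Three structural quantities are extracted:

1. **Protected-fragment size.** A double-stranded fragment sequenced from
   both ends leaves a plus-strand tag at its left end and a minus-strand tag
   at its right end. The Pearson correlation between the plus-strand count
   vector and the minus-strand vector shifted by `d` therefore peaks near
   the fragment length (an `L`-bp fragment places the two 5'-ends `L - 1`
   apart, so the estimate is one below the physical length - well inside
   the reported precision). A second, *technical* peak appears at the read
   length because unique-alignment constraints correlate mappability on the
   two strands; it is excluded by a +/-5-bp band around the read length.
2. **Spacing periodicity.** Protected fragments recur at a characteristic
   center-to-center distance. Same-strand autocorrelation (computed per
   strand and averaged) turns this into regularly spaced local maxima; the
   dominant period of the mean-subtracted profile's Fourier power spectrum,
   searched over 50-500 bp, quantifies it.
3. **Clusters of resistance.** Tags are shifted by half the fragment size
   to strandless fragment centers; a Gaussian kernel density (sigma = 25 bp)
   of the centers is thresholded at an empirical positionwise FDR of 10^-3
   against uniform-placement randomizations, runs are merged (< 25-bp gaps)
   and length-filtered (>= 25 bp), and calls not enriched over the
   naked-DNA control are discarded.

Around gene boundaries, accessibility appears as dips in the fragment-center
metagene profile; sequence context is profiled in parallel (GC content and
A-tract frequency), because MNase prefers AT-rich DNA and A-tracts
(`AnTm` runs, associated with intrinsic curvature) concentrate in promoters.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `z_threshold` | 7 | SD | anomalous tag pile-up filter |
| `max_lag` (cross / auto) | 500 / 1000 | bp | lag ranges; the auto range spans >10 spacing periods |
| `window` (correlation) | 25 | bp | running-mean smoothing of correlation profiles |
| `read_length` +/- 5 | 36 | bp | technical-peak exclusion band |
| `period_range` | 50-500 | bp | periodogram search range |
| `bandwidth` | 25 | bp | Gaussian KDE sigma for fragment centers |
| `fdr`, `n_rand` | 10^-3, 20 | - | empirical FDR target and randomization count |
| `min_length`, `merge_gap` | 25, 25 | bp | cluster run rules |
| `min_ratio` | 1.0 | - | nucleoid/control enrichment floor |
| `flank`, `window` (profiles) | 500, 50 | bp | metagene window and smoothing |
| tract bounds | 3-10 | bp | reported `AnTm` total-length range |
| `n_rand` (tracts) | 15 | - | shuffled genomes for the genome-to-random ratio |

The Z-score statistics are computed **per strand over occupied positions
only** (count >= 1). Over all positions the genome-wide mean count is far
below one, and a threshold of 7 SD would flag nearly every duplicated
position - the opposite of the filter's purpose, which is to remove rare
amplification spikes. Pooled-strand and include-zero variants are exposed as
flags (`pool_strands`, `include_zeros`). Duplicate tags at one position are
counted, not collapsed: the filter removes positions, not reads.

# The synthetic-data generator

No raw sequencing data accompany the study conditions this package targets,
so the generator *is* the study preset, and its defaults are fixed once:

- 1-Mb circular genome at GC 0.51, 500 non-overlapping genes of 0.6-1.8 kb;
- 50-bp footprints in clusters of 2-5, centers spaced exactly 93 bp apart,
  at 0.5 clusters/kb (about one per 2 kb, ~9% of the genome protected - the
  protected fraction is not constrained by any measurement, and ~10% is a
  deliberate free modeling choice);
- fragment boundaries jittered (Gaussian, SD 3 bp); a plus tag always at
  the fragment's left end, a minus tag at its right end with probability
  0.5; 200,000 tags per sample;
- accessibility dips: fragments whose center falls within 50 bp of a TSS or
  TES are rejected with probability 0.6;
- A-tracts planted at loop apexes (the gaps between successive footprints
  of a cluster, Poisson rate 1 per apex) and at 3x that rate in the
  [-100, +20] promoter window, total length uniform on 3-10 with a uniform
  A/T split, flanked by forced non-A/T bases so each planted tract is
  maximal and recovered exactly by the scanner;
- a control sample of fragments placed uniformly (with a 1.5x cut-rate
  preference at A/T start positions) with lengths uniform on 50-500 bp -
  no characteristic length, no periodicity;
- amplification artifacts: ~10^-5 of positions per strand spiked to >= 50x
  the occupied-position mean, recorded for QC verification.

One global seed feeds a fixed per-stage substream scheme (stage k uses seed
`(seed + k * 1299709) mod (2^31 - 1)`), so each stage is independently
reproducible and every generator is a pure function of (config, seed).

**What the generator does not emulate.** No base-calling errors, no FASTQ,
no mappability structure - hence no technical read-length peak in the
synthetic cross-correlation (the band is still excluded, as for real data).
Real genomes carry a large excess of A-tracts over shuffled sequence
(genome-to-random ratio above 3 for 8-bp tracts); i.i.d. background
sequence cannot and should not reproduce that, so tests of the ratio
statistic use planted tracts, and the genuine genomic excess can only be
checked against the real genome sequence. Passing recovery tests therefore
demonstrate estimator correctness under the generative model, not the
biological claims themselves.

# Numerical choices

- **Correlations via FFT.** On a circular genome, all lagged Pearson
  correlations are computed at once from circular cross-covariance sums via
  the FFT; means and population SDs are constant under rotation, so the
  result is exact (it matches an `O(nk)` `cor()`-on-rotations oracle to
  10^-10). Linear genomes fall back to truncated-overlap correlation.
- **KDE without truncation.** The density is an exact circular convolution
  with the fully wrapped Gaussian kernel (again via FFT), so density mass
  equals the center count to ~10^-10 and the track matches a naive double
  loop at the same precision. Nothing is gained by tail truncation at
  genome sizes up to several Mb.
- **FDR calibration.** Exceedance curves for the observed track and for
  `n_rand` uniform multinomial placements of the same number of centers are
  tabulated on a 2048-point threshold grid; the threshold is the smallest
  grid value where mean null exceedance <= fdr x observed exceedance. If no
  grid point qualifies, the threshold is set just above the observed
  maximum: an empty call set, not an error. Per-position FDR is used; a
  per-cluster variant was considered and rejected as underdetermined.
- **Periodogram grid.** The spectrum is evaluated with 4x zero-padding by
  default: at 1000 lags the raw Fourier grid brackets a 93-bp period with
  ~9-bp spacing, while padding refines the argmax to ~2 bp. At
  `oversample = 1` the power at each Fourier frequency equals the explained
  sum of squares of a least-squares sinusoid fit, which is how the
  periodogram is validated.
- **Peak acceptance.** A fragment-size candidate must be a local maximum of
  the smoothed profile (this rejects shoulders of the excluded technical
  band) and must rise above the median of the searched profile by at least
  half its height above the minimum. The naked-DNA control produces a broad
  low plateau (uniform fragment lengths spread the cross-correlation over
  the whole 50-500-bp range) whose maximum sits near the plateau median and
  is rejected, yielding the no-estimate result; a genuine fragment peak
  towers over the median by design.
- **Smoothing.** Running means are centered; even window widths are rounded
  up to odd, and edges use truncated windows. Metagene smoothing of 50 bp is
  thus effectively 51 bp.
- **Control enrichment.** Densities are normalized to per-million centers;
  a pseudo-density of 1/genome-length is added to both numerator and
  denominator so that control-free regions stay finite and identical tracks
  give a ratio of exactly 1 at the `min_ratio = 1` boundary.
- **Coordinates.** 0-based half-open everywhere internally; BED is written
  0-based, GFF3 1-based, via rtracklayer. A minus-strand tag's 5'-end is
  the rightmost aligned base (`chromEnd - 1` in BED, alignment end in
  SAM/BAM), matching standard aligner semantics.

# Design decisions on genuinely open points

- *Cross-correlation definition.* Full-count-vector Pearson correlation,
  not a nearest-opposite-strand-tag distance histogram; the former is the
  established cross-correlation methodology in tag-based sequencing QC, and
  the schematic "closest tag" picture is treated as illustrative.
- *Strand handling in autocorrelation.* The two strands' profiles are
  averaged (each is also returned); with ~100k tags per strand the averaged
  profile halves the noise without biasing the period.
- *Loess span.* The A-tract TSS profile is loess-smoothed with span 0.1
  over the 1001-point window - wide enough to suppress per-offset binomial
  noise across 500 genes, narrow enough to keep the ~100-bp promoter
  feature.
- *Randomized genomes.* Uniform permutation of the genome's own bases,
  preserving mononucleotide composition exactly; i.i.d. resampling at the
  same composition is available as an option. Higher-order (di/trinucleotide)
  preservation is deliberately not implemented.
- *Gene sets.* Genes anchor the profiles directly; no operon
  reconstruction, no exclusion of genes overlapping other genes' flanks (a
  flag-level extension if ever needed).

# Known limitations

- Called clusters on the default simulation are a few hundred bp long
  (median ~280 bp): the 2-5 planted footprints of a cluster, spaced 93 bp,
  merge under the 25-bp kernel because inter-footprint gaps stay above the
  FDR threshold. Recovery is therefore scored against planted *clusters*
  (>= 80% at >= 50% reciprocal overlap; measured ~99%), and cluster-length
  distributions are not comparable across generative regimes with different
  footprint multiplicities.
- The periodogram argmax is quantized by the (padded) Fourier grid; on the
  preset it lands within ~2 bp of the planted 93-bp spacing, varying with
  the seed over 90.9-95.2 bp.
- Multi-chromosome inputs are handled by iterating independent sequences;
  there is no joint normalization across records.
- Problem sizes throughout (1-Mb genome, 200k tags, 20 FDR randomizations,
  15 shuffles) are the package's documented study preset; estimator
  behavior at other scales follows the usual root-n statistics but is not
  separately calibrated.
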