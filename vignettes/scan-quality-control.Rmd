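---
title: "Scan-series quality control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-series quality control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanqc)
```

## The problem and the model

Ambient-ionization sources spray analytes directly from minimally prepared
samples, so a five-minute measurement of one tissue fragment yields a series
of several hundred scans whose peak-intensity ratios fluctuate with the
spray. Most scans reflect the sample's molecular profile; a minority are
measurement artifacts — anomalous local maxima or minima in the total ion
current from unstable spray, gas bubbles, or signal dropouts. `scanqc`
treats a measurement as a time-ordered series of spectrum vectors and asks
two questions: how self-consistent is the series (stability), and how
consistent are repeated measurements of the same sample (reproducibility)?

Each centroided scan is mapped to a fixed-dimension vector by summing peak
intensities into half-open m/z bins `[edge, edge + width)`. Two scans are
compared by Pearson's r (mean over the full grid, zeros included) or the
cosine measure. For sparse nonnegative spectra the grid mean is nearly zero,
so the two metrics nearly coincide; the cosine needs no centering and is
preferred for the 120 000-dimensional default grid. Both metrics are
invariant to any positive rescaling of either vector, so variations in total
ion current alone — and TIC normalization — do not affect them.

Artifact filtering scores each scan by its cosine against a reference: the
mean of the moving-median-smoothed series. The per-bin median over an odd
window of `N` scans ignores any artifact run of at most `⌊N/2⌋` consecutive
scans, so the reference is built from the stable behaviour of the series and
artifact scans stand out as low scores. Scans below a threshold are
rejected; the survivors are averaged into the consensus spectrum assigned to
the measurement.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `mz_min`, `mz_max` | 100, 1300 Da | grid limits; peaks outside are dropped and tallied |
| `bin_width` | 0.01 Da | matched to ~2 ppm mass precision at the high end of the range, so binning roughs the data no further than the measurement itself |
| `window` | 51 scans | about one minute of acquisition at ~1 Hz; rejects artifact runs up to 25 scans. 21 behaves almost identically at lower cost; 5–7 let single-scan instabilities through |
| `step` | `window` | non-overlapping windows for global sample grouping; `step = 1` keeps full temporal detail for inspecting profile changes within a run |
| `metric` | cosine | Pearson's r available throughout; values are near-identical on real spectra |
| `threshold` | `"auto"` | `min(median − 3·MAD, median/2)`, clamped to [0, 1]; any fixed value in [0, 1] may be given |

## The automatic threshold

Score distributions vary with instrument, sample and spray stability, so the
default threshold is data-driven. The scale-adaptive part is the classic
robust rule `median(scores) − 3·MAD(scores)` (MAD scaled by 1.4826 as in
`stats::mad()`): when scores are tight and unimodal it sits just below the
bulk and catches even moderate outliers.

That rule alone, however, misbehaves under a real property of fixed-grid
binning: a strong peak whose true m/z lies within the mass-precision jitter
of a bin edge lands in one of two adjacent bins scan by scan. Scans holding
the minority bin lose that peak's entire contribution against the
median-built reference, producing a heavy-tailed or bimodal score
distribution in which a sizeable fraction of perfectly good scans scores
0.6–0.8 while the bulk sits near 0.98. A bulk-scale rule then rejects good
scans wholesale. The `median/2` cap expresses the judgement that a scan
retaining at least half the typical similarity to the reference is not a
measurement artifact, whatever the spread of the bulk; genuine artifacts
(foreign profiles, dropouts) score near zero and remain far below it.
Degenerate (all-zero) scans are rejected unconditionally.

The cap has a cost: when the score distribution is tight, a subtly
off-profile scan scoring, say, 0.8 is kept. It also does not rescue the
rare pathological series in which a *dominant* peak straddles an edge
almost 50/50 — there even the reference is degraded, the MAD term collapses
the threshold to 0, and zero-score artifacts slip through. The
artifact-recovery rate that `scripts/acceptance.R` computes over 20 seeded
runs quantifies how often this occurs under the default generator settings;
a fixed threshold (e.g. 0.3) is the pragmatic override for such series.

## The reference spectrum

"Aggregate of the smoothed scans" admits two readings: (a) the mean of the
moving-median series, or (b) a smoothed version of a single aggregate.
Reading (b) collapses to one spectrum with nothing left to smooth over, so
(a) is implemented: `reference = mean(moving_median(series))`. Scoring uses
the cosine, not Pearson's r, as the scan-versus-reference comparison.

## The synthetic generator

`generate_measurement()` emulates one acquisition: 300 scans of a 50-peak
profile with peak positions uniform over m/z 100–1300 and log-normal base
intensities (`sdlog = 1`, giving the few-dominant-peaks structure typical of
lipid profiles); per-peak multiplicative log-normal noise (`noise_sigma`,
default 0.1); per-scan log-normal scale fluctuation (`scale_sigma`, default
0.2) emulating spray-current variation; optional linear drift toward a
second profile (off by default; set `drift_rate` to emulate sample
exhaustion at the end of a run); and uniform m/z jitter within 2 ppm — small
enough to stay within a 0.01 Da bin at low m/z, large enough to hop bins
near m/z 1300, deliberately exercising bin-boundary behaviour. Artifact
scans replace normal ones as foreign profiles (unrelated random profile),
TIC spikes (10× scale plus extra peaks) or TIC dropouts (0.01× scale). All
draws come from one seeded Mersenne-Twister stream; the same seed reproduces
the measurement exactly, and the returned ground truth (per-scan noiseless
profile, scale factors, artifact indices) makes every downstream claim
checkable.

`generate_study()` shares one base profile across the fragments of a sample
(fresh noise per fragment) and draws independent profiles for distinct
samples, emulating a fragments-within-samples tissue-profiling design.

What the generator does *not* emulate: isotope patterns, adducts or
lipid-class m/z structure; correlated (non-independent) scan noise;
partial peak overlap between distinct samples — independently drawn 50-peak
profiles share essentially no bins, so between-sample similarity is ~0,
whereas real tissues share abundant common lipids and show intermediate
similarity. Passing tests on synthetic data therefore demonstrate the
mechanics of binning, metrics, smoothing and filtering — not that any
particular threshold or window is optimal for a given instrument.

## Numerical choices

- **Half-open bins** `[edge, edge + width)`: every in-range m/z maps to
  exactly one bin; `floor()` assignment is guarded against float round-up at
  the top edge. Co-binned peaks are *summed*, conserving in-range TIC and
  making TIC normalization exact.
- **Sparse semantics, dense contract.** Spectra store only positive bins;
  all operations reproduce dense-grid results exactly. Pearson's r uses
  `Σ(X−X̄)(Y−Ȳ) = ΣXY − N·X̄·Ȳ`; the matrix path computes one sparse Gram
  matrix (`Matrix::crossprod`) and derives both metrics from it. Tests pin
  sparse results to dense brute-force evaluation at 1e-12.
- **Sparse moving median with implicit zeros**: a bin present in fewer than
  `(window+1)/2` of the window's scans has median 0 and is never
  materialized; otherwise the median is read off the sorted nonzero values
  at rank `(window+1)/2 − (window − count)`. Windows are leading (anchored
  at `(k−1)·step + 1`), only full windows are emitted
  (`⌊(n − window)/step⌋ + 1` outputs), and even windows are rejected so the
  median is always a single observed value.
- **Degenerate comparisons** (all-zero vector; for Pearson, any constant
  vector) return 0 with a degeneracy flag instead of NaN, keeping matrices
  renderable and making degenerate scans visible as low-similarity bands.
  A variance that cancels to within 1e-14 of zero relative to `ΣX²` is
  treated as zero.
- **Stored values are never clamped**; negative Pearson values are clamped
  to 0 only in heatmaps, whose color scale is fixed to [0, 1] and shared
  across all figures of a report.
- **Empty scans** (no in-range peaks) are retained and flagged by default —
  they carry timing information and are visible as bands — with a
  `drop_empty_scans` switch to remove them up front.

## Problem sizes

The test suite and the acceptance script run at the scale the method
targets: 300-scan measurements with 50-peak profiles; the full window grid
{5, 7, 21, 51} × steps {1, half, full}; 20 seeded recovery runs; a
2-samples × 2-fragments study (1200 × 1200 similarity matrices on the
120 000-bin grid). Oracle-equivalence checks use random grids up to 1000
bins where dense brute force is cheap.

## Known limitations

Fixed-width binning is brittle for peaks near bin edges (see the threshold
discussion); ppm-adaptive binning or peak alignment would remove this but is
out of scope. The method assigns one profile per measurement: heterogeneous
samples whose profile genuinely changes mid-run (drift) are flagged as
low-stability rather than split into segments. mzML input must be
centroided; profile-mode data are rejected rather than centroided silently.
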