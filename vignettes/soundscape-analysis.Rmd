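---
title: "Methods: from long-term recordings to frequency correlation matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from long-term recordings to frequency correlation matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundscapeFCM)
```

## The problem

Scheduled passive acoustic monitoring produces months of fixed-length
recordings per site — far too much audio to listen to, and too much even to
display as a conventional spectrogram. The question this package addresses
is how to characterise the *acoustic environment* of a site over such a
period: which frequency bands carry power, how that power moves over days
and seasons, and which bands move together because the same (or co-occurring)
sound sources occupy them.

The pipeline reduces each recording to a binned power spectrum, stacks the
spectra of one site into a time-ordered ensemble, cleans that ensemble, and
summarises it three ways:

1. a **median power spectrum** with a 5–95% quantile band;
2. a **normalised spectrogram** — daily mean power per frequency bin,
   min–max scaled to [0, 1] bin by bin over the whole period;
3. a **frequency correlation matrix (FCM)** — the squared Pearson
   correlation between every pair of bin power time series, with its
   histogram of off-diagonal values.

The FCM is the analytic core: blocks of mutually high $R^2$ ("frequency
communities") indicate sound sources whose occurrences are linked at the
recording time scale, and its dimension depends only on the bin count, not
on the number of recordings.

## Choosing the frequency binning

Storing full-resolution spectra for months of audio is wasteful, but
aggressive binning erases spectral structure. The bin count $B$ is chosen by
scanning candidate counts and tracking two complexity measures over a sample
of recordings:

* **mean intra-bin variance**
  $\bar v_B = \frac{1}{n}\sum_{i=1}^n \frac{1}{B}\sum_{b=1}^B
  \operatorname{var}(s_{ib})$,
  the (population) variance of the spectral power values inside each bin,
  averaged over bins and recordings — the complexity a binning throws away;
* **mean Shannon evenness**
  $\bar H_B = \frac{1}{n}\sum_{i=1}^n
  \left(-\sum_b p_{ib}\ln p_{ib}\right)/\ln B$ with
  $p_{ib} = \bar s_{ib} / \sum_{b'} \bar s_{ib'}$,
  the entropy of the binned, sum-normalised spectrum — 1 for a flat
  spectrum, 0 when one bin holds everything.

For each measure the successive absolute changes along the scan are divided
by their maximum; the selected $B^\*$ is the smallest scanned count from
which on *both* relative-change series stay at or below the threshold
(default 10%), optionally rounded up to a power of two for storage. Two
numerical details are fixed deliberately: the variance is the population
variance (the defining formula carries no sample-size correction), and the
saturation comparison is "at or below" the threshold so that a vacuous
threshold of 1 selects the first scanned count.

The evenness is computed on the normalised binned spectrum. A literal
single-mean variant ($-\bar s\,\ln \bar s$ on the grand mean of the bin
means) is exposed as `spectral_entropy_literal()` for comparison; it is not
the entropy of a distribution, is not scale-invariant, and is not used by
the pipeline.

How large a sample of recordings the scan needs is answered by Cochran's
formula with finite-population correction,
$n_0 = z^2 \cdot 0.25 / e^2$, $n = n_0 / (1 + (n_0 - 1)/N)$:
`cochran_sample_size(0.01, 0.99, 416797)` gives 15,953, i.e. 16,000 to the
nearest thousand.

Saturation is a property of *structured* spectra. For an i.i.d. spectrum the
intra-bin variance declines linearly in $B$, so its relative change never
falls below any threshold — there is nothing to saturate. The packaged
sampler (`simulate_spectrum_sample()`) therefore draws spectra around a
smooth urban-like envelope (steep low-frequency roll-off, mid- and high-band
humps; `urban_reference_spectrum()`) with 20% multiplicative log-normal
noise, and uses 65,536 spectral points so that even the largest scanned
count keeps ~16 points per bin — short spectra would enter a single-point
regime at the top of the scan where evenness never settles. On that sample,
a 50-count scan from 50 to 4000 bins saturates at $B^\*=614$, i.e. 1024
after power-of-two rounding, stably across seeds.

## Cleaning the ensemble

Binned spectra are log10-transformed (with a floor of $10^{-12}$ times the
maximum bin power, so empty bins stay finite), because variability differs
by orders of magnitude between low and high frequencies.

**Denoising.** Each bin's power time series is denoised by truncated PCA:
the series is arranged as a days × within-day-slots matrix (the `daily`
embedding; scheduled monitoring records ~50 slots per day, and the diurnal
cycle is the dominant low-rank structure), columns are centred, and the
smallest number of leading components whose cumulative explained variance
reaches 95% is kept; the matrix is reconstructed from those components. The
discarded ≤5% of variance is treated as noise. An SSA-style `lag` embedding
is available where no regular daily schedule exists. Missing cells are
imputed with the bin median for the decomposition only and restored
afterwards — denoising never invents data. The reconstruction is standard
truncated PCA (scores already carry the eigenvalue scale); an additional
literal eigenvalue re-weighting of each component is available behind
`eigen_weighting = TRUE` for comparison, but it distorts amplitudes and is
not the default.

**Outlier removal.** Rare, very loud events (sirens, direct impacts) survive
denoising as isolated excursions. Per bin and site, values strictly above
the empirical 99.95% quantile (type-7 interpolation, as everywhere in the
package) are set to missing. A constant series loses nothing; the removal
count per bin is bounded by roughly $(1-q)\,n$. Removed cells become `NA`
rather than being clipped or deleted row-wise, and all downstream statistics
use the available data per bin or per pair.

The pipeline order is fixed and recorded in each ensemble's provenance:
`bin → log → pca_denoise → outlier_removal`. PCA runs on log power (the log
transform precedes it in the pipeline), and normalisation happens after
outlier removal.

## Summaries and the FCM

The median (not the mean) summarises per-bin power because of its robustness
to the same loud events; the 5–95% band shows the range. Daily mean spectra
are computed per calendar date (local time, no timezone arithmetic), with
maintenance days kept as missing rows so gaps stay visible. Per-bin
normalisation is min–max (0 = the bin's period minimum, 1 = its maximum):
a divide-by-maximum alternative would leave the lower anchor undefined,
whereas min–max yields a testable contract and makes weakly powered
high-frequency bins as legible as dominant low-frequency ones.

The FCM squares the Pearson correlation, so anti-correlation is folded in
(the signed matrix can be retained with `keep_signed = TRUE` for
diagnostics). Entries use pairwise-complete observations because outlier
removal leaves scattered missingness; entries backed by fewer than
`min_pairs` (default 30) complete pairs, and rows of zero-variance bins, are
`NA` — never silently zero. Analyses are capped at 13 kHz by default, the
band below which built environments hold nearly all acoustic power; the cap
is configurable. The $R^2$ histogram tallies the strict upper triangle into
50 half-open bins on [0, 1] (last bin closed); multimodality indicates
several distinct groups of interlinked bins. `block_contrast()` quantifies a
proposed community partition as mean within-block minus mean between-block
$R^2$, and `histogram_modes()` locates local maxima for multimodality
checks.

## The synthetic soundscape generator

No study data ship with the package, so every stage is validated on
synthetic ground truth. A scenario is a set of band-limited sources, each
with a relative power and an occupancy schedule (diurnal hour window,
weekday mask, optional calendar window, per-slot occurrence probability).
Two tiers generate data:

* the **spectral tier** (`simulate_ensemble()`) writes each active source's
  level into its band's bins on top of a flat noise floor, takes log10, and
  adds independent Gaussian noise (default sd 0.25 log-units) — fast enough
  for property tests;
* the **waveform tier** (`synthesize_wav()`) renders active sources as
  band-passed white noise via FFT-domain masking with raised-cosine edges,
  so WAV I/O and the spectrum estimators are exercised end to end.

Both tiers share the schedule logic and the noise floor (0.003 linear power,
about 25 dB below a unit source per Hz — chosen once so that a single active
source dominates the total power of a recording, as a prominent source does
in practice), and they agree on the expected band lift of
$\log_{10}(1.003/0.003) \approx 2.52$ decades.

`default_urban_scenario()` plants three communities emulating recurring
urban patterns: a weekday-only source below 2.5 kHz (road traffic and its
weekly rhythm), a season-windowed morning source at 2.5–8.5 kHz (breeding
birdsong), and an evening source at 9–11 kHz (crickets), over 30 days × 50
slots × 64 bins — sized to run the full pipeline in well under two minutes
on one core. Co-activity is independent Bernoulli per slot modulated by the
schedule masks; that is sufficient to induce the block-correlation structure
the FCM is designed to reveal, which is exactly what the end-to-end tests
check (block contrast ≥ 0.4 against the truth partition, a bimodal $R^2$
histogram, a weekend dip in the low band of the normalised spectrogram).

What the generator does **not** emulate: realistic source timbres or
temporal envelopes (everything is shaped noise), propagation and weather
effects, correlated source schedules beyond shared masks, device artefacts
(wind rumble, clipping), or diurnal drift of the noise floor. Passing tests
therefore demonstrate that the pipeline recovers planted co-occurrence
structure under realistic bookkeeping (schedules, gaps, missingness) — not
that it identifies real-world sources.

## Spectrum estimation details

`power_spectrum()` offers two estimators. `welch` (default) averages
modified periodograms over 1-s Hann segments with 50% overlap and returns a
density (sum × Δf ≈ variance); it is the right choice for multi-minute
recordings because single-FFT periodograms of noise-like signals have
100% relative variance per point. `fullfft` is the single
rectangular-window FFT of the whole recording, normalised so the one-sided
power sums to the signal's mean square (Parseval, checked to 1e-6 in the
tests). Binning uses contiguous runs of spectral points, `floor(n/B)` or
`ceil(n/B)` points per bin with the larger bins first — a deterministic,
documented remainder rule — and conserves total mean power exactly.

## Problem sizes and runtime

Defaults are sized for a laptop core: the bin-count scan uses 200 spectra of
65,536 points over 50 counts (~25 s); the default scenario is 1,500
recordings × 64 bins (seconds through the whole pipeline); tests build all
fixtures programmatically and finish in under a minute. The same code scales
to study-sized inputs (10⁵ recordings, 1024 bins) by streaming recordings
per site; per-recording spectra are independent, so processing order is
irrelevant.

## Known limitations

* The daily PCA embedding assumes an (approximately) regular recording
  schedule; heavily irregular schedules should use the `lag` layout.
* Squaring the correlation discards the sign; genuinely anti-correlated
  bands (e.g. masking effects) look like communities.
* Pairwise-complete correlations are not guaranteed to form a positive
  semi-definite matrix; the FCM is a descriptive summary, not a covariance
  estimate for downstream factor models.
* Community structure is assessed against a *given* partition
  (`block_contrast()`); automatic community detection on FCMs is out of
  scope.
* Calibration to absolute sound pressure (dB SPL) is out of scope; all
  power is relative, which is also why per-bin normalisation and Pearson
  correlation — both invariant to per-bin affine maps — are the summaries
  of choice.
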