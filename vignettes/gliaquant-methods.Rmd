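---
title: "Quantifying microglial dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

gliaquant quantifies how microglia — the brain's resident immune cells —
behave during ocular dominance plasticity experiments: how ramified their
process arbors are in fixed tissue, how motile the processes are in vivo,
how strongly they converge on a focal laser injury, how much receptor-labelled
material they engulf, how cortical responses shift between the two eyes,
and how often their processes contact synaptic elements in electron
micrographs. Every stage has a matching synthetic-data generator with
recorded ground truth, so the whole pipeline can be validated end to end
without animal data. This vignette describes each method, its assumptions,
the tunable parameters, and the design decisions that were genuinely open.

## Sholl morphometry

A binarized arbor mask is sampled with concentric circles around the soma
(default every 5 µm, matching the granularity at which ramification
profiles are usually reported). The crossing count at radius *r* is the
number of maximal 8-connected runs of foreground pixels along the
midpoint-rasterized circle of that radius; runs wrapping the 0°/360° seam
are merged. This is the standard discrete Sholl definition; it is testable
against a brute-force oracle that walks the circle pixel by pixel, and the
package's run counter agrees with that oracle on randomized arbors and on
dense random masks.

Profiles are computed on 2D maximum projections, not in 3D: arbors in thin
projections are effectively planar and every downstream comparison is
between profiles, not absolute 3D branch counts. Binarization
(`binarize()`) offers the triangle method, Otsu's method, or a fixed value,
always applied strictly-greater-than, followed by an artefact filter that
drops connected components below `min_size` pixels (default 4 px — the
original analyses only state that artefacts were filtered, so the size
floor is configurable, not data-derived). Cells clipped by the image border
should be excluded by the analyst; the function does not guess.

One caution on an intuitive-sounding invariant: total crossings are *not*
monotone under arbitrary pixel removal — deleting a mid-run pixel splits
one run into two. Removing entire branches does reduce (or preserve) the
total, and that is the property the test suite asserts.

## Time-lapse motility indices

The motility pipeline mirrors the classic RGB-overlay analysis of
two-photon time-lapse projections (12 frames at 4- or 5-min cadence):

1. register the projections (translation only),
2. threshold them once (threshold taken from the first frame and reused,
   so that index changes reflect morphology rather than threshold drift;
   per-frame thresholding is available),
3. classify each consecutive pair of masks pixel-wise: *stable* (foreground
   in both), *extended* (second only), *retracted* (first only),
4. per overlay, motility index = (extended + retracted) / stable,
   extension index = extended / stable, retraction index =
   retracted / stable, each averaged across overlays.

Indices are reported per interval (change per 4 min), not per minute,
following the convention in which they are usually plotted. The stability
index of consecutive overlays is the fraction of newly extended pixels that
are stable in the next overlay; the instability index is the fraction of
stable pixels that retract. Both are undefined when their denominator is
empty and are returned as `NA` — never coerced to 0 — and omitted from
averages. An interval with zero stable pixels stops the analysis with an
error naming the interval, since the index is undefined there.

The stability histogram follows every pixel that turns extended→stable at
some overlay (its first such transition) and reports the fraction still
*continuously* stable 1, 2, … overlays later, excluding pixels stable for
the whole session (somata and primary processes, which would otherwise
dominate the curve).

Two design choices deserve explanation:

* **Threshold flavour.** The movie pipelines default to Otsu's method
  rather than the triangle method. The triangle construction places the
  cut near the background shoulder (≈2.5 noise s.d. above background).
  With realistic noise — up to 10% of the foreground level — that leaves
  enough background flips adjacent to the arbor to inflate
  extension/retraction counts by several percent per interval; Otsu's
  mid-valley cut leaves ≈4 s.d. of margin on both sides. On synthetic
  movies the pipeline then recovers planted indices exactly at zero noise
  and within ~2% at 10% noise. The triangle method remains available and
  is the default where it is the prescribed method (engulfment scoring,
  below).
* **Registration.** Motion correction is translation-only, integer-pixel,
  estimated by FFT cross-correlation on mean-subtracted frames.
  Spectrally whitened (phase-only) correlation was tried first and
  rejected: when ~20% of foreground pixels turn over per interval it can
  mis-report ±1 px shifts on drift-free movies, which poisons every
  pixel-level count. Shifts are estimated between consecutive frames and
  accumulated, because consecutive frames differ by only one interval of
  drift and turnover. Pixels invalidated by shifting are excluded from all
  counts via a validity mask. Each pairwise estimate carries a
  peak-ratio confidence; low-confidence estimates are flagged, never
  silently dropped — whether a shaky movie is usable is the analyst's
  call.

The traced-process measure (`traced_motility()`) is independent of
thresholding: for a manually traced process it is the mean of
|ΔL| / interval over consecutive time points, in µm/min.

## Laser-ablation response

The chemotactic response to a focal injury is
R(t) = (Rx(t) − Rx(0)) / Ry(0), where Rx counts thresholded foreground
pixels in the inner disc of radius X (default 40 µm) and Ry(0) counts the
outer annulus X < r ≤ Y (default Y = 80 µm) at the first time point. The
inner compartment is the full disc rather than a thin ring: processes
"entering" the inner radius accumulate there, and a disc counts each pixel
once. A small core around the lesion centre (default 5 µm) is excluded so
the lesion itself is never counted. Distances use centre-of-pixel
positions in µm. Degenerate geometry (inner ≥ outer, core ≥ inner, annulus
leaving the image) is rejected, never reinterpreted. R(0) = 0 by
construction; Ry(0) = 0 is an error because the normalizer is undefined.

## Engulfment (colocalization) scoring

Two-channel z-stacks are smoothed (2D Gaussian per plane, default σ = 1 px;
the source protocol says only "smoothed"), triangle-thresholded per channel
— the one stage where the triangle method is the prescribed choice — and
multiplied. Internalized puncta are connected components of the product
mask strictly larger than `min_punctum_px` pixels (default 1, i.e. the
"larger than 1 pixel" rule read as ≥ 2 px). Components connect across
z-planes with 26-connectivity, since puncta in a 0.5-µm-step stack span
planes; single planes use 8-connectivity. The density normalizer is the
total area of the cell-channel mask; by default that is the per-plane sum
(a 3D-consistent measure), with the projected 2D area available as an
option since the original description does not say which was used.

The triangle threshold itself is implemented from the histogram geometry:
the line from the histogram peak to the farthest non-empty tail bin, the
threshold being the bin at maximal perpendicular distance from that line,
mirrored when the long tail is on the left, with ties broken toward the
peak (the more inclusive mask). It is verified against a brute-force
point-to-line-distance oracle on randomized histograms.

## Ocular dominance index

Each pixel's reflectance time series is Fourier-transformed and the
amplitude at the bin nearest the stimulus repetition frequency is
normalized as 2·|X[k]|/N, so a pure sinusoid of amplitude A yields exactly
A ("normalized amplitude"). A per-pixel linear detrend is available (off
by default) for slow hemodynamic drift. Per eye, responses to the upward
and downward stimulus sweeps are averaged over the binocular-zone ROI; the
ROI is user-supplied, with a fallback that keeps pixels above a fraction of
the maximum mean amplitude. The ocular dominance index is
ODI = (C − I) / (C + I), in [−1, 1], positive for contralateral bias. The
stimulus repetition frequency is a required parameter — it depends on
screen geometry and sweep speed, which the acquisition, not the analysis,
determines. Phase maps fall out of the same transform and are returned,
but no retinotopic analysis is built on them.

## EM event statistics

Per-process event counts (cleft contacts, inclusions, element contacts …)
are divided by the traced process area in µm², averaged within animal, and
summarized per group as mean ± s.e.m. with the *animal* as the unit of n.
A one-pass Grubbs test (G = max|xᵢ − x̄|/s against
G_crit = ((n−1)/√n)·√(t²/(n−2+t²)), t the α/(2n) quantile at n−2 df)
optionally removes a single extreme per-process density — the documented
use case being an exceptionally small traced area that turns a few events
into a huge density. It is applied exactly once, never iterated, per
category by default. Sidedness is a flag (two-sided default, α = 0.05);
the original description suggests only large values were targeted but does
not say, so the conservative two-sided form is the default.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed, and its
ground truth is recomputed from the generated arrays (not from the
construction), so tests never trust bookkeeping:

* `generate_arbor()` — soma disc plus straight 1-px, 4-connected rays at
  well-separated angles; a ray of length L crosses every circle of radius
  < L exactly once, so Sholl truth is analytic. Ray lengths keep 2 px
  clearance from every sampling radius so discretization cannot flip a
  crossing; angular separation keeps distinct rays from merging into one
  run on the smallest circle (which caps how many branches fit at a given
  minimum radius).
* `generate_timelapse()` — 12 frames at 4-min cadence by default. Each
  interval removes a fraction of the foreground at process tips (pixels
  with ≤ 1 foreground 4-neighbour) and adds a fraction at background
  4-neighbours of the surviving foreground; retraction is sampled first so
  an added pixel can never be orphaned by the simultaneous removal of its
  anchor. The exact added/removed/stable pixel sets are the oracle for the
  motility indices. Frames render at background 60 / foreground 240 with
  optional Gaussian noise clipped to [0, 255]: the nonzero background
  emulates a detector offset, and matters — a zero background piles ~half
  of all background pixels into one histogram bin under additive noise and
  defeats every histogram-shape threshold.
* `generate_ablation_movie()` — radial segments slide toward the centre at
  a fixed rate and halt at the excluded core, so foreground translocates
  rather than grows. Segments occupy windows of distance-ordered,
  pairwise-disjoint ray rasters, which makes the inner-disc count exactly
  non-decreasing for inward motion — the monotonicity the response curve
  should show.
* `generate_puncta_image()` — multi-pixel puncta planted wholly inside or
  wholly outside a cell disc, with margins and pairwise separation chosen
  so smoothing cannot move a punctum across the mask edge or merge two
  puncta.
* `generate_ios_session()` — per pixel, DC + A·sin(2πft + φ) + noise, with
  the duration an integer number of stimulus periods so the stimulus falls
  on an exact FFT bin and the planted amplitude is recovered exactly at
  zero noise.
* `generate_event_table()` — Poisson counts with mean = density × area,
  the model the area normalization assumes; areas uniform on a configurable
  range, 50–88-ish processes per animal at the original scale.

What the generators deliberately do **not** emulate: point-spread-function
blur, photon shot noise, depth-dependent attenuation, 3D arborization, or
vascular shadows. Passing tests therefore demonstrate that the
*quantification* is correct given reasonable imagery — not that the
pipeline is robust to every acquisition pathology of real two-photon or
intrinsic-signal data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col); physical quantities are carried in
  µm and minutes and converted only at pixel boundaries.
* Thresholds apply strictly-greater-than everywhere.
* Constant (featureless) images: `binarize()` warns and returns an empty
  mask so batch runs survive blank fields; the colocalization and ablation
  entry points raise instead, because their downstream normalizers would
  be meaningless.
* Undefined ratios (zero stable pixels, empty extension cohort, zero
  Ry(0), C + I = 0, Grubbs with zero variance) raise or return `NA`
  according to whether the whole analysis (error) or a single summary
  value (`NA`) is affected.
* TIFF round-trips are bit-exact for integer data: samples are written
  as stored and read with `as.is = TRUE`.

## Problem sizes used in tests

The test and acceptance workloads run on ~63–181 px images, 12-frame
movies, 25–100 synthetic arbors, 1000-sample property sweeps, and EM
tables up to 1000 processes × 5 animals × 2 groups. These sizes were
chosen to exercise every code path and drive sampling error well below the
asserted tolerances while keeping the default suite fast on one CPU.
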