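---
title: "Quantifying focal adhesion turnover and peripheral trafficking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focal adhesion turnover and peripheral trafficking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Migrating cells advance by assembling integrin-based focal adhesions (FAs)
at the protruding edge and disassembling them as the cell body follows.
Scaffold proteins at the plasma membrane (liprin-α1, ERC1 and their
partners) specifically promote the *disassembly* side of this cycle, and
perturbing them leaves assembly untouched while adhesions become
longer-lived and accumulate at the periphery, together with Rab7-positive
late endosomes. Testing such claims quantitatively requires a pipeline
that can (i) measure per-adhesion assembly and disassembly rates from
time-lapse fluorescence, (ii) decompose three-channel colocalization into
exclusive combinations, (iii) split the cell footprint into a peripheral
band and a central region, and (iv) do all of this reproducibly, with
known ground truth to validate every stage. `fadyn` implements that
pipeline together with a seeded synthetic-microscopy generator, so each
measurement can be checked against the truth that generated the images.

## Turnover from kymographs

The core measurement follows the kymograph protocol used in live-cell FA
studies. For each tracked adhesion a straight line of 10 µm is traced
along its axis of growth and the image is resampled along that line once
per frame, producing a position × time matrix. The distal tip (pointing
toward the nearest cell edge) and the proximal tip are located per frame
at the half-maximum crossing above background: within a column, the
adhesion extent is the contiguous run of positions at or above
`background + 0.5 · (column max − background)`, and both run ends are
refined to sub-sample precision by linear interpolation. The assembly
rate is ΔD/ΔT of the distal tip during extension; the disassembly rate is
ΔD/ΔT of the proximal tip during retraction; halt time is the portion of
the adhesion's life in neither state; lifespan is the time the adhesion
is visible within the acquisition (capped at its 60 min duration).

Design choices that needed fixing beyond the protocol's wording:

* **Detection and tracking.** Adhesions are segmented with one shared
  threshold per series (Otsu on the pixel-wise max projection, then
  applied fixed to every frame — the same-threshold-for-all-conditions
  rule made reproducible), labelled 8-connected with a minimum area of
  0.2 µm², and linked frame-to-frame greedily by footprint
  intersection-over-union, ties broken by centroid distance and then
  label order. Gaps of up to one frame are bridged. Tracks touching the
  first or last frame are flagged censored; censored lifespans are
  reported but a caller can exclude them from summaries.
* **Growth axis.** The principal axis of the union of a track's
  footprints, oriented so that the positive direction points to the
  nearest cell-edge point. For nearly isotropic unions the axis falls
  back to net centroid displacement. The line is frozen at track birth so
  that ΔD is measured against a fixed ruler.
* **Event segmentation.** A tip series is cut into maximal runs of
  advancing steps; a run of at least `min_duration = 3` frames whose mean
  rate reaches `min_rate = 0.05` µm/min is an event. Two refinements keep
  ΔD/ΔT faithful at 1 frame/min sampling: steps are classified by a local
  windowed slope (±2 steps) *or* their own step rate, which prevents a
  slow event's onset from dissolving into the halt; and the rate window
  is trimmed of boundary steps slower than 80% of the run's median step,
  because an interval in which motion stops midway otherwise dilutes the
  rate of short events by up to ~20%. Halt accounting uses the untrimmed
  moving extent, so trimmed boundary frames are not misbooked as halt.
  No numeric stability criterion is stated in the source protocol; these
  defaults distinguish halt from drift and are exposed as configuration.
* **Accounting identity.** Per track, event time + halt time +
  undefined-tip time equals the observed lifespan exactly; simultaneous
  assembly and disassembly intervals are unioned before the subtraction.
  Event counts are reported both raw and normalised to 60 min of
  observation, since the protocol does not say which normalisation its
  per-hour counts used.

## Colocalization by exclusive mask algebra

Three binary channel masks A, B, C are decomposed into the 7 exclusive
combinations (A-only, B-only, C-only, AB, AC, BC, ABC), which partition
their union; AB excludes ABC by construction. Within analysis regions the
package reports, per combination, pixel counts and each channel's
integrated density, and expresses the 4 combinations containing a channel
as fractions of that channel's in-region total. The additivity identity —
the 4 densities of channel X sum exactly to X's masked in-region density —
holds bit-exactly on integer images and is enforced by tests.

Regions follow both of the protocol's descriptions side by side, since
they are not equivalent: each reference adhesion dilated by a disc of
0.8 µm (realised pixel radius recorded), and a 5 × 4 µm rectangular crop
centred on the adhesion, aligned with its major axis by default
(axis-aligned crops available — the protocol does not say which was
used). Overlapping neighbourhoods are evaluated independently and
flagged. Fractions default to integrated densities (intensity-weighted);
a pixel-count mode mirrors analyses run on thresholded masks.

## Peripheral band and enrichment statistics

The central region is defined by the offset curve equidistant 10 µm from
the cell edge. It is computed with a Euclidean distance transform — a
geometric, isotropic offset — rather than iterated structuring-element
erosions, which are anisotropic. Distances are corrected by half a pixel
because the transform measures to the nearest *background pixel centre*,
which lies half a pixel beyond the true mask boundary; with this
correction a 50 × 30 µm rectangle with a 10 µm band yields exactly the
300 µm² core that plane geometry requires, and the transform agrees
exactly with a brute-force per-pixel minimum-distance oracle. Pixels at
exactly the band width belong to the central region (≥ rule). Peripheral
signal is total-in-cell minus central, normalised to the cell area, for
binary areas or integrated densities alike; signal outside the cell is
counted in neither and reported separately. Per-adhesion vesicle
intensities reuse the 0.8 µm neighbourhoods (window size configurable;
the source protocol does not state the window it used) and classify each
adhesion by its centroid's membership in the partition.

## Cell morphometrics

Projected area is the foreground pixel count times the pixel area.
Circularity is 4πA/p², reported raw (digitised near-circles may slightly
exceed 1). The perimeter defaults to a sub-pixel contour: the mask is
Gaussian-smoothed and contoured at the 0.5 level by marching squares
with linear interpolation. Pixel-edge ("crack") perimeters inflate p so
strongly that a digitised disk's circularity drops by tens of percent,
which is why the smooth contour is the default; the crack mode is kept
for parity with pixel-edge measurements. The smoothing scale adapts to
object size (σ = √area_px/20 px, clamped to [0.8, 3]) so that the same
shape rasterised at twice the resolution changes its measured perimeter
by well under 1%; a fixed small σ would leave a 2× upsampled mask's
staircase under-smoothed and its perimeter ~2–3% high. Aspect ratio uses
the equivalent-ellipse axes from second central moments with a 1/12 px²
per-pixel variance term, which regularises collinear masks to a finite
ratio.

## The synthetic-data generator

The generator emulates the study conditions: a 60-frame acquisition at
1 frame/min; elongated adhesions near the cell border that extend
distally at `v_assembly`, halt, then retract proximally at
`v_disassembly`; punctate vesicles with a tunable peripheral placement
bias; and three-channel fields with prescribed exclusive overlap
fractions. No pixel size is stated for the source acquisitions; the
default 0.16 µm/px is a convention for a 1.4–1.49 NA / 63–100× system
and is flagged in the configuration. Defaults for the kinetics are
assembly 0.1–1.0 µm/min, disassembly 0.05–0.5 µm/min, ribbon width
0.6 µm, final lengths 2.5–3.8 µm — plausible magnitudes for FA turnover
at a protruding edge. Final length grows with `v_assembly` so each
assembly phase spans at least ~3.5 frames, the minimum for a measurable
event at `min_duration = 3`; appearance times are staggered over minutes
2–6 and halts last 5–12 min, so each adhesion shows all three phases
within the hour. Disassembly runs until the ribbon is consumed;
adhesions outliving the acquisition carry censoring flags.

Rendering integrates photon flux over each pixel: ribbon coverage is
computed on a 4 × 4 subpixel grid, so edges move continuously rather than
one pixel at a time. This matters: with binary footprints, tip positions
quantise to the pixel grid and both slow-event onsets and short-event
rates degrade measurably. Objects are summed, blurred with a Gaussian PSF
(default 1 px), a constant background is added, and noise follows the
standard fluorescence model — Poisson on scaled counts then Gaussian read
noise (the source states no noise model). With the defaults
(`peak = 100`, `background = 10`, `poisson_scale = 1`) the peak
signal-to-noise ratio is ≈10. All randomness flows from one seed through
counter-based per-object substreams, so adding an object never reshuffles
the draws of existing ones, and identical (spec, seed) reproduce stacks
bit-identically.

The truth tables mark a frame `present` when the rendered footprint
reaches 0.2 µm² — the size below which a structure would not be scored as
an adhesion — matching the detection minimum, and record per-frame tip
positions and footprint sizes. The three-channel generator places each
exclusive combination as 10 × 10 px patches on a staggered grid with
one-block gaps, so PSF blur from one patch never reaches a patch of a
different combination and border-pixel noise (which transfers double
combinations to singles at patch rims) stays below half a percentage
point on the recovered fractions.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: photobleaching, stage drift,
multi-cell fields, 3D PSF anisotropy, adhesion splitting/merging,
intensity maturation gradients within an adhesion, and motile adhesions
that translocate rather than grow/shrink along a fixed axis. Recovery
numbers here bound what the pipeline can do under its own model, not
under every microscope.

## Validation summary

The test suite checks, at fixed seeds chosen as part of the study
conditions: circularity's closed forms (circle 1, square π/4, 4:1
rectangle 16π/100); recovery of 30 simulated adhesions' rates within
10%, lifespan within ±1 frame and halt within ±2 frames (noiseless,
1 px PSF); the silencing signature (disassembly halved → lower
disassembly, assembly within 5%, longer lifespan; three seed-matched
replicate pairs); exact agreement of the exclusive-mask algebra with a
per-pixel oracle on 1000 random instances plus bit-exact additivity;
recovery of prescribed overlap fractions within 2 percentage points at
SNR ≈ 10; exact equality of the band partition with an O(N²) oracle on
50 random blobs plus the exact rectangle example; and peripheral
enrichment (bias 0.8 vs 0.0 greater in 5/5 replicates; a 2× per-adhesion
density recovered within 10%). `scripts/acceptance.R` recomputes all of
these from scratch at a caller-supplied seed. Problem sizes (300² px
stacks, 30 adhesions, 64² oracle instances, 60² blobs) were chosen so the
whole validation completes in a few minutes on one core.

## Known limitations

* Lifespan recovery is typically exact to ±1 frame, but for the
  slowest-growing adhesions the detected footprint can cross the
  detection threshold one frame before truth visibility at each end;
  across many seeds the error occasionally reaches 2 frames. Halt-time
  errors behave similarly: usually within ±1 min, occasionally slightly
  above 2 min when a slow, censored disassembly shrinks an adhesion
  toward the resolution limit. Columns whose measured extent falls below
  about twice the PSF FWHM are treated as undefined rather than
  stationary, which keeps most of that bias out of the halt estimate.
* ΔD/ΔT rates at 1 frame/min sampling are limited by partial boundary
  intervals; the median-based trim removes most of the bias but assumes
  events have a roughly steady rate.
* The greedy tracker does not resolve adhesion splitting or merging; the
  colocalization report treats overlapping neighbourhoods independently
  rather than apportioning shared pixels.
* Otsu-based batch thresholds assume the first frame (or max projection)
  is representative of the series' intensity distribution.
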