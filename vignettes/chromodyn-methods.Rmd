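---
title: "Models and methods behind chromodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

chromodyn quantifies the assays used to characterise the material state of
pericentromeric heterochromatin (chromocenters) in mouse embryonic stem
cells and how major satellite repeat (MSR) transcripts regulate it. This
vignette explains the models each module fits, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## FRAP: correction, normalization and the one-phase association model

A FRAP acquisition yields three per-frame intensities: the bleached
chromocenter ROI, an unbleached control chromocenter, and a background
region. `correct_trace()` computes

$$N(t) = \frac{(I_B(t) - I_{bg}(t)) / (I_C(t) - I_{bg}(t))}
              {\langle \text{same ratio} \rangle_{pre}},$$

so that the pre-bleach mean is exactly 1. Dividing by the control ROI
cancels any multiplicative trend shared by the ROIs, in particular
monoexponential acquisition bleaching; `use_control = FALSE` skips that
division for protocols summarised as raw median intensity. Both the fully
corrected fit and the raw median summary (`frap_raw_median()`, labelled
`corrected = FALSE`) are always available, since published FRAP panels mix
the two conventions.

`fit_recovery()` fits the post-bleach frames with the one-phase association

$$Y(x) = Y_0 + (P - Y_0)\,(1 - e^{-Kx}),$$

where $x$ is time since the first post-bleach frame. Fitting uses
Levenberg–Marquardt least squares with the plateau re-parameterised as
$P = Y_0 + \Delta$, $\Delta \ge 0$, and $K > 0$; initialization takes $Y_0$
from the first post-bleach value, $P$ from the mean of the final 10% of
frames, and $K$ from the observed half-rise time, with jittered restarts on
failure and an explicit `converged` flag instead of silent values. Because
fitting uses the actual timestamps, nonuniformly sampled protocols (two
1-s baseline frames, then one frame every 5 s) are handled exactly.

Derived quantities follow their defining formulas: half-time
$t_{1/2} = \ln 2 / K$ and mobile fraction
$F_m = (P - I_{first\,post}) / (I_{pre} - I_{first\,post})$. The first
post-bleach value in $F_m$ is the *observed* corrected value, not the fitted
$Y_0$ (the two differ under noise; the fitted $Y_0$ is reported separately).
Noise can push $F_m$ slightly outside $[0, 1]$, so it is clamped with a
warning rather than failing.

## Tracking and event calling

`detect_foci()` thresholds each frame (one constant threshold per movie) and
reports intensity-weighted centroids. `link_tracks()` assigns detections to
tracks frame by frame with the Hungarian algorithm on gated Euclidean
distances (`clue::solve_LSAP`), closes gaps up to `max_gap_frames`, and,
when merge/split resolution is on, calls:

* **coalescence** — a track that loses its detection while ending within the
  gate of a detection claimed by another track is merged into it;
* **cleavage** — an unmatched detection appearing within the gate of a track
  matched in the same frame seeds a child track.

The default gate is three times the median frame-to-frame nearest-neighbour
displacement estimated from the data; every analysis here states the gate it
used explicitly (1.2 µm for the bundled time-lapse conditions). Event
engagement (`event_engagement()`) counts, per cell, the fraction of tracks
of duration ≥ 10 min that participate in at least one event, summarised
across cells as a median with interquartile range. Each participant track
counts once per event; the continuation of a merge is the surviving track,
so a fusion engages both parents. This convention matters when comparing
absolute engagement numbers and is fixed throughout the package.

## MSD and anomalous diffusion

`msd()` computes the time-averaged mean squared displacement
$\mathrm{MSD}(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle_t$ on complete,
uniformly sampled tracks, with lags capped at 25% of the track length — long
lags average few displacement pairs and dominate the estimator variance
otherwise. `fit_msd()` estimates the anomalous exponent $\alpha$ and
apparent diffusion coefficient $D_{app}$ by linear regression of
$\log \mathrm{MSD}$ on $\log \tau$ under the 2D model
$\mathrm{MSD} = 4 D_{app} \tau^{\alpha}$. Velocity comes from a separate
directed-diffusion fit $\mathrm{MSD} = 4D\tau + (v\tau)^2$ with nonnegative
coefficients (`pracma::lsqnonneg`); since the velocity model is a
convention rather than a derived result, a model-free
net-displacement/duration estimate is reported alongside. Single-track
$\alpha$ estimates scatter substantially (SD ≈ 0.12 at 310 frames); the
estimator is validated on the *mean* over tracks.

## Segmentation, morphometry and colocalization

`segment_nuclei()` estimates the background as a percentile (default the
median) of out-of-nucleus pixels — found via a two-stage Otsu split so that
bright chromocenters and nucleoplasm do not inflate the estimate — then
applies two constant offsets above background: a low one for nuclei and a
higher one for chromocenters. The offsets are deliberately required
arguments: the appropriate constant depends on the acquisition and must be
held fixed across a batch for comparisons to be meaningful. Additive
intensity offsets cancel by construction.

`morphometry()` measures each chromocenter at its mid-section, defined as
the z-plane maximizing its cross-sectional area ("optimal focal plane";
single-plane images use that plane). The major axis is that of the
second-moment ellipse: axis length $4\sqrt{\lambda}$ for covariance
eigenvalue $\lambda$, exact for an ideal ellipse. Areas are reported in both
pixels and µm². Coordinates are 1-based (y, x) following R array
conventions; quartile comparisons (`quartile_bin()`) define bin boundaries
on the reference condition and assign boundary ties to the lower bin.

Pixelwise Pearson colocalization (`pearson_colocalization()`) is computed
per chromocenter over mid-section pixels; zero-variance chromocenters are
excluded and counted. Linescans sample channels along a user-defined segment
with bilinear interpolation, average across the line width, and min-max
normalize per channel; flat profiles return zeros with a warning rather
than dividing by zero.

## RNA-FISH localization classes

`classify_overlap()` implements the three-way rule on per-chromocenter
overlap fractions of each focus: *within* when >50% of the focus overlaps
one chromocenter, *between* when it overlaps at least two chromocenters each
by <50%, *periphery* when it overlaps exactly one by <50%. Two boundary
conventions had to be fixed: exactly 50% goes to the sub-50% branch (the
rules as stated are strict inequalities and leave equality unaddressed), and
a focus touching no chromocenter is reported as a fourth class,
*unassociated*, with the three main classes expressed as fractions of
associated foci. Overlaps are computed on the focus mid-section, matching
the area convention.

## Droplet plates

`detect_droplets()` thresholds each well image, labels components, filters
by circularity ($4\pi A / P^2 \ge 0.6$) and equivalent-circle diameter
(≥ 1 µm by default), with the default threshold placed midway between the
image median and maximum so detection is invariant to global gain.
"Detectable droplets" is operationalised as ≥ 5 droplets per field — the
underlying experimental readout is visual, so both the count and diameter
cutoffs are exposed as parameters. `call_critical_concentration()` returns
the minimum tested concentration with detection and flags non-monotone
detection patterns along the dilution series as QC failures instead of
silently reporting a minimum. Concentrations are handled on the scale given
in the plate layout (the 2× labels of the dilution series); the equal-volume
1× final concentration is carried alongside as metadata.

## FLIM

`build_two_level_mask()` separates heterochromatin spots from euchromatin
inside segmented nuclei by difference-of-Gaussians spot detection; the two
masks are disjoint and their union is the nucleus. `pool_and_fit()` sums the
photon histograms of a region and fits $c(t) = A e^{-t/\tau} + b$ by Poisson
maximum likelihood — preferred over weighted least squares because tail bins
hold few photons and Gaussian weights misbehave there. Without an IRF the
fit starts one bin after the histogram peak (tail fit); with an IRF the
model is convolved with it over the full curve. Laser-period wraparound
(25 ns at 40 MHz) folds the decay back into the window; because the folded
exponential keeps the shape $e^{-t/\tau}$ on $[0, T)$, the tail fit remains
unbiased (verified by simulation up to τ = 5 ns). Per-image region
lifetimes — not pixels — are the statistical unit in condition comparisons.

## The synthetic-data generator

Every analysis above can be exercised end to end on generated inputs with
known ground truth. Named presets (one editable YAML registry,
`inst/extdata/presets.yaml`) encode the emulated conditions:

* **FRAP**: the TALE-reporter condition acquires 1 frame/s for 310 s with 10
  pre-bleach frames; control kinetics place the half-recovery at ~30 s
  ($K = \ln 2 / 30$) with a 25% immobile fraction, and the MSR-depleted
  condition doubles the recovery time with a 30% immobile fraction. The
  HP1α-reporter condition uses 2 baseline frames at 1 s then one frame per
  5 s for 61 s, with $t_{1/2}$ of 8 vs 13 s and immobile fractions of 15% vs
  26% for control vs MSR-depleted. Bleach depth (0.3–0.35), acquisition
  bleaching (5 × 10⁻⁴ – 2 × 10⁻³ s⁻¹) and 2% multiplicative noise are not
  printed quantities; they were chosen once as typical of spinning-disk
  FRAP at these exposure levels.
* **Motion**: fractional Brownian motion generates anomalous diffusion —
  the standard stationary-increment model when only an MSD exponent is
  specified — scaled so MSD$(\tau) = 4 D_{app}\tau^{\alpha}$, plus optional
  drift. Exact simulation by Cholesky factorisation of the fractional
  Gaussian noise covariance (tracks are ≤ ~400 frames, so exactness is
  cheap).
* **Time-lapses**: 20-min movies at 30-s intervals, ~11 (control) or ~14 (MSR-depleted) foci per nucleus in
  a 7-µm-radius projected nucleus at 0.25 µm/px. Fusion and fission are
  scheduled as a Poisson process; a fusion steers the nearest partner into
  contact at a bounded approach speed, a fission displaces daughters by one
  blob radius along the axis with most clearance, and a soft
  volume-exclusion constraint keeps unrelated foci from drifting into
  unresolvable contact — so every visual merge corresponds to a scheduled
  event and remains resolvable by the tracker. The fusion/fission rates of
  the two conditions (0.0100 and 0.0048 events per focus per minute for
  each kind, control and MSR-depleted respectively) were calibrated once by simulation so that the *measured*
  per-cell engagement of ≥10-min tracks — through detection, linking and
  event calling — matches the observed ~45% (control) and ~25%
  (MSR-depleted) engagement, and then frozen in the registry. Movies are
  rendered directly as 2D maximum-intensity-projection views, matching how
  the motion is analysed.
* **Nuclei and RNA foci**: 16-µm mid-section nuclei at 0.1 µm/px with ~8
  chromocenters (control) or more, smaller ones (MSR-depleted). Each RNA
  focus samples its class from the preset probabilities — (0.17, 0.64,
  0.19) for the control condition — and is placed so its true pixel-overlap
  fractions satisfy the class rule with a safety margin; a few
  near-touching chromocenter pairs are placed deliberately so the *between*
  class is always geometrically feasible, and foci keep a minimum mutual
  distance so detection resolves them. Absolute intensities are arbitrary
  units throughout: the cellular MSR RNA concentration is unknown, so only
  ratios and geometry are meaningful.
* **Droplet plates**: two-fold dilution series from 200 µM down to 1.6 µM
  plus 0. Wells at or above a species' critical concentration receive
  ~25 disks with lognormal diameters around the species' size scale;
  forward-strand species get larger scales than reverse-strand at matched
  repeat number, longer repeats get lower critical concentrations, and the
  no-RNA row never forms droplets.
* **FLIM**: multinomial photon draws from a binned, period-folded
  exponential, 256 bins over 25 ns. SiR-DNA lifetimes of 2.4/2.0 ns
  (euchromatin/heterochromatin, control) and 2.35/1.90 ns (MSR-depleted)
  represent the compaction ordering; the exact nanosecond values are
  representative of SiR-DNA in cells rather than printed numbers.

What the generator does **not** emulate: realistic optics (the PSF is an
isotropic Gaussian; no depth attenuation, no camera-specific noise
calibration), 3D diffusion (blobs move in the projection plane), chromatin
texture inside nuclei, spectral bleed-through, or a measured IRF shape
(synthetic validation uses delta and Gaussian IRFs). Passing tests therefore
demonstrate that the estimators are correct and well-calibrated on data
satisfying their model assumptions — not that segmentation thresholds or
tracking gates transfer to any particular microscope without adjustment.

## Numerical choices and degenerate inputs

* FRAP fits refuse fewer than 8 post-bleach frames; non-convergence after
  restarts returns `converged = FALSE`, never silent numbers.
* MSD fits drop nonpositive values before taking logs and refuse fewer than
  5 remaining lags; stationary tracks yield MSD ≡ 0 and are caught there.
* The FLIM fitter optimises log-parameters with box bounds (τ ∈ [0.05,
  100] ns) and flags bound-hitting fits; it refuses pooled histograms under
  1000 photons.
* Mann–Whitney tests are exact below 50 observations per group without
  ties, and use the normal approximation with tie/continuity correction
  otherwise (`stats::wilcox.test` semantics).
* Empty segmentations warn and return empty label maps; cells without
  qualifying tracks are excluded from engagement with a warning.

## Problem sizes used in the bundled checks

The test suite and the acceptance script regenerate everything they
measure: 50 TALE and 2 × 45 HP1α FRAP traces, 100 time-lapse nuclei per
dynamics condition, 100 fBm tracks of 310 frames, ~110 nuclei (500+ RNA
foci), 100 random droplet plates, and up to 10⁶-photon FLIM histograms.
These sizes were chosen to keep Monte-Carlo error comfortably below the
tolerances being checked.

## Known limitations

* The tracker is greedy per frame-pair with one-frame lookback for events;
  it does not globally optimise track topology as a full LAP tracker does,
  and crossing trajectories faster than the gate will swap identities.
* The velocity estimate inherits the directed-diffusion convention; for
  strongly subdiffusive tracks the fitted $v$ is a small-sample upper bound
  rather than a physical speed.
* Critical-concentration calls are limited to the tested grid by
  construction; they cannot interpolate between dilutions.
* The classifier depends on segmentation quality: heavily eroded
  chromocenter masks shift *between* foci toward *periphery*. The bundled
  presets keep segmentation near-exact; real data will not.
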