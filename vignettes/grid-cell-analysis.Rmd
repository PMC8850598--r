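---
title: "Grid-cell network analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cell network analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridcells)
```

This vignette is the package's account of the science it implements: the
models and estimators, their assumptions, the tunable parameters with
their defaults and units, what the synthetic generators do and do not
emulate, and the choices made where the methodology left the design
open.

## The scientific setting

Grid cells in the medial entorhinal cortex (MEC) fire at the vertices of
a hexagonal lattice tiling the environment, and are thought to support
path integration — navigation by accumulated self-motion. In
amyloid-pathology mouse models their spatial periodicity degrades with
age while other spatial cell types (head-direction cells, non-grid
spatial cells, CA1 place cells) remain comparatively intact, and homing
behavior deteriorates in parallel. Quantifying this requires a chain of
estimators — rate maps, autocorrelograms, gridness, shuffle nulls,
epoch-wise stability, rhythm, synchrony, behavioral metrics — each of
which this package implements and validates against synthetic data with
known ground truth.

## Preprocessing

Two tracking diodes at ~30 Hz give position (their centroid) and head
direction (the red-to-green angle, 0° along +x, counterclockwise).
Dropout runs of up to 5 samples are filled by linear interpolation —
circular interpolation (via unit vectors) for direction, so a gap
spanning 359°→1° fills near 0°, never 180°. Longer runs stay missing and
are excluded. Running speed comes from a constant-velocity Kalman filter
(process noise 10 cm/s², measurement noise 0.5 cm; both exposed). The
filter matters for speed-resolved analyses: raw finite differences
inflate the speed of a stationary animal with tracking jitter, while the
filtered estimate converges to truth within ~1 s for straight running.
Results at 30 Hz are insensitive to moderate changes in the two noise
parameters.

## Rate maps and derived statistics

Maps use 3 × 3 cm bins. A bin counts as *visited* at ≥ 100 ms occupancy
(`min_occupancy`, exposed; the methodology is silent here). Spikes are
assigned to the bin of their nearest trajectory sample, which makes the
unsmoothed map conserve the spike count exactly — an invariant the tests
assert as an integer identity. Smoothing is a truncated Gaussian
(SD 3 bins = 9 cm, radius 3 SD) renormalized over visited bins: our
reading of a "pseudo-Gaussian" kernel, and the most common one. Exact
mass preservation under this renormalization holds only away from mask
edges (the tests check it on interior-supported rates); at edges the
renormalization slightly inflates mass, as it does in every
mask-normalized smoother.

Spatial information is the Skaggs statistic in bits/spike. Split-half
reliability correlates the smoothed maps of the session halves over
mutually visited bins. Field detection thresholds connected components
at 50 % of each local peak; the normalized field size divides the mean
field area by spacing² — a dimensionless choice that makes the statistic
invariant to rescaling field size and spacing together. The exact
normalization behind the published field-size figure is not stated; ours
is a documented convention, not a transcription.

## Gridness

The spatial autocorrelogram is the masked Pearson correlation of the
smoothed map with itself at every 2-D lag (≥ 20 overlapping bins per
lag), computed via FFT cross-correlations of the masked arrays. The six
local maxima nearest the center — outside the central field, delimited
by the first zero crossing of the angularly averaged correlation — seed
an origin-centered ellipse fit. Moderate eccentricity is corrected by
compressing the autocorrelogram along the major axis by minor/major;
when the minor axis is under half the major axis no correction is
applied (the map is scored as-is and flagged). The annulus runs from the
central-field radius to the farthest inner-peak radius plus the
central-field radius — our reading of "a ring that encased the six
peaks"; the exact width rule is an interpretation and is carried in the
result object.

The rotational correlation is evaluated on a polar resampling of the
annulus (radial step 0.5 bin, angular step 3°), where a rotation is an
exact circular shift of the angular index and samples are weighted by
radius to match the uniform-pixel definition. This choice is deliberate:
rotating the Cartesian image instead treats 90° (pixel-exact) and 60°
(interpolated) differently, which biases the 60°-vs-90° contrast at the
heart of the score. A concentric-ring autocorrelogram — rotation
invariant by construction — scores ≈ 0 under the polar scheme, as it
should. The score itself is

> gridness = min(r₆₀, r₁₂₀) − max(r₃₀, r₉₀, r₁₅₀),

and 0.54 is the operative grid threshold. The tests pin the
implementation against an independent, literal transcription of the
procedure (nearest-neighbor rotation, plain `cor()`), within 0.05 on
analytic hexagonal fields.

## Classification

Shuffle nulls circularly shift all spike times by U(30 s, T − 30 s), 50
times, and take the type-7 (linear-interpolation) 99th percentile; with
n = 50 the percentile rule matters, hence it is pinned by a sort-based
oracle in the tests. Defaults follow the dataset-wide fixed thresholds
(gridness 0.54, MRL 0.21) with per-cell recomputation available —
reproducibility of the published pipeline plus correctness on new data.
Putative interneurons (waveform < 0.3 ms, mean rate ≥ 0.5 Hz) are
evaluated first and excluded from the spatial classes; the
grid/interneuron precedence is not stated in the methodology and this
ordering is our interpretation. Grid and head-direction labels may
co-occur (conjunctive cells); non-grid spatial requires failing the grid
gate with split-half ≥ 0.6. The speed score smooths spike counts with a
250 ms Gaussian (unspecified in the methodology; exposed) before
correlating with speed.

## Stability

Ten 3-min epochs (other partitions are a parameter change) give per-pair
masked cross-correlograms over ±5-bin lags. Within the window, pixels at
≥ 50 % of the maximum qualify; the qualifying pixel nearest the center
(ties by angle) seeds a 4-connected patch — 4- rather than
8-connectivity, the stricter reading — and the patch maximum defines the
displacement. For an all-negative window only the maximum itself
qualifies. Rotation is searched over ±30° (one lattice symmetry sector)
in 3° steps, with translation re-optimized at each candidate angle,
since the methodology does not state whether rotation was optimized
jointly with translation.

## Rhythm

The theta-by-speed spectrogram computes Morlet power (ω₀ = 6) at 0.25 Hz
steps from 1–15 Hz — the stated "0.25 Hz bandwidth" is ambiguous between
wavelet bandwidth and frequency sampling; we read it as the sampling
step and expose ω₀. Each LFP sample's spectrum is divided by its own
delta power (2–4 Hz mean) and then averaged within 2 cm/s speed bins
from 2–30 cm/s (bins under 5 s of data are flagged); normalizing per
sample before averaging is our resolution of the unstated order of
operations. Theta power is the 7–12 Hz mean; theta frequency is the
5–15 Hz peak per speed bin, with the discrete argmax refined by
quadratic interpolation of log power. The refinement is needed on
scientific grounds: baseline-frequency effects of ~0.2 Hz are below the
0.25 Hz grid, and a bare argmax quantizes frequency differences to
multiples of 0.25 Hz; parabolic peak interpolation is standard spectral
practice and recovers the offset to within a few hundredths of a Hz.

Intrinsic frequency bins spikes at 5 ms, autocorrelates over ±1 s, zeros
the self-count lag, smooths (2-bin SD), mean-subtracts, applies a single
Slepian taper (NW = 3, computed from the tridiagonal formulation),
zero-pads to 2¹³, and takes the periodogram peak in 6–12 Hz
(resolution ≈ 0.024 Hz).

## Synchrony

Cross-correlograms count spike-time differences in 5 ms bins over
±400 ms and divide by T − |lag| (overlap/triangular correction — the
"unbiased" estimator; the exact published estimator is not spelled out
and this is our documented reading). After 25 ms-SD Gaussian smoothing
(the stated "25 ms gaussian" read as the SD, truncated at 3 SD), the
correlogram is normalized as a robust z-score: centered on its median
and scaled by its raw median absolute deviation (constant = 1). Pure
division by the MAD would rank flat, independent pairs *above*
synchronous ones (a large mean over a tiny MAD), inverting the meaning
of the statistic; median-centering restores it — independent pairs
fluctuate about zero, synchronous pairs show a positive central peak,
anti-synchronous pairs go negative. The figure-caption variant
("normalized by median") is available via `normalize = "median"`. The
MAD is computed over the full ±400 ms vector, center included.
Co-activity is the mean normalized correlation within ±25 ms.

## Path integration

The homing arena is a regular decagon of 63.8 cm diameter with one wall
as the refuge door. Wall contact uses a 2 cm distance (unstated;
exposed), the initial heading uses the first 10 cm of path (unstated;
exposed), and the thigmotaxis band is 15 % of the circumradius
(~4.8 cm; unstated; exposed). Angles are reported as absolute values in
[0°, 180°] — whether the published angles were signed is not stated.
Return paths are defined from pellet pickup to refuge entry; trial
annotations are inputs, not inferred.

## The synthetic generators

The generators exist so that every estimator has a recovery test; their
defaults are the study conditions the tests run under.

- **Trajectory**: Ornstein–Uhlenbeck speed (mean 15 cm/s, SD 6 cm/s,
  τ = 1 s, clipped at 0) with Gaussian-increment heading
  (1.5 rad/√s) and specular wall reflection, sampled at 30 Hz. The
  speed range matches foraging mice (analyses use 2–30 cm/s), and the
  defaults give full 3 cm-bin coverage of a 75 cm box within 20 min —
  the coverage contract of the recording protocol (water droplets
  scattered to enforce full-field sampling).
- **Grid cells**: three-cosine hexagonal lattice raised to a sharpness
  exponent (default 2), peak rate at nodes, optional elliptic stretch.
  Phase drift is a per-minute cumulative 2-D Gaussian walk with
  per-minute displacement variance drift_rate² — step-wise rather than
  continuous, matching the 3-min epoch resolution of the stability
  analysis it stresses. No quantitative drift magnitude is available for
  pathological grid cells, so drift scales are free parameters exercised
  over {0, 5, 10, 20} cm/min in the tests.
- **Spiking**: inhomogeneous Poisson by thinning at 1.05 × the observed
  rate bound, with a 1 ms refractory period so autocorrelograms are
  realistic near zero lag.
- **Head direction / interneurons / place cells**: von Mises tuning,
  sinusoidally theta-modulated Poisson, and Gaussian fields.
- **LFP**: instantaneous frequency = base + gain × speed(t), integrated
  phase, additive Gaussian noise.
- **Homing trials**: pellet uniform in the interior (5 cm wall margin),
  heading toward the refuge with von Mises error (≥ 180° means uniform),
  straight run to first wall contact, then wall-following the short way
  to the refuge. The thigmotaxis bias parameter makes a trial
  wall-seeking with the given probability.

What the generators deliberately do *not* emulate: attractor-network
dynamics, theta phase precession, conjunctive tuning interactions,
waveform voltages, behavioral state changes, or any biological drift
mechanism. Passing recovery tests therefore demonstrates estimator
correctness on data with the assumed statistical structure — Poisson
spiking on smooth rate fields, sinusoidal LFP — not robustness to every
property of real recordings.

## Numerical choices and degenerate inputs

- Masked Pearson correlations (autocorrelograms, epoch
  cross-correlograms) are computed with zero-padded FFTs; the tests pin
  them to a brute-force loop oracle at 1e-8.
- Lags with < 20 overlapping bins, constant overlap regions, annuli
  with < 50 valid pixels per rotation, zero-MAD correlograms, zero-mean
  rate maps, and empty trial lists are all flagged (NA + condition)
  rather than silently scored.
- Percentiles use type-7 linear interpolation everywhere.
- Ellipse fits use least squares on the conic through the six peaks;
  degenerate fits fall back to uncorrected scoring, flagged.
- Fixed seeds give bit-identical generator output; all generator
  functions restore the caller's RNG state.

## Problem sizes

The test suite validates at the study scale: 20 cells per condition for
grid recovery and drift degradation (30-min sessions), 100 cells for
intrinsic-frequency discrimination, 100 pairs per synchrony condition,
~10⁵ spikes for the Bessel-ratio MRL checks, and 500 homing trials for
the geometric chance-level comparison. `scripts/acceptance.R` re-derives
the same quantities at moderately reduced counts (e.g. 10 recovery
cells, 8 cells per drift level, 40 pairs) chosen to keep a full
reproduction run in the low minutes on one CPU; both scales recover the
same ground truth within the stated tolerances.

## Known limitations

- The gridness rotational correlation uses polar resampling; scores
  match a literal image-rotation transcription to ~0.05 on clean fields
  but are not bit-identical to implementations that rotate the Cartesian
  image.
- Field-size normalization (area / spacing²) and the annulus width rule
  are documented interpretations where the methodology is silent.
- The Kalman filter assumes near-uniform sampling; heavily irregular
  timestamps would need a time-varying transition matrix.
- Epoch maps shorter than ~3 min of coverage per epoch can leave
  unvisited bins that shrink the usable lag window for displacement.
- No spike sorting, duplicate-cell deduplication across days, or native
  acquisition-format readers; sessions enter through the documented
  open bundle layout or in-memory objects.
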