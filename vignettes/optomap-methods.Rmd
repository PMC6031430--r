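---
title: "Methods: behavior-space phenotyping of optogenetically stimulated flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior-space phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(optomap)
```

# The problem

Optogenetic screens drive a genetically targeted set of neurons with
light and ask what the animal does in response. When the neurons under
study are descending neurons — cells relaying commands from the brain to
the motor centers — the honest answer is "anything a fly can do", and a
supervised classifier built around preconceived behavior categories
would miss phenotypes it was never taught. `optomap` implements the
unsupervised alternative: every video frame of a freely moving fly is
mapped into a two-dimensional *behavior space* in which nearby points
are frames with similar postural dynamics, and the effect of
stimulation is read out as a shift of the fly's probability density
over that space. On top of the map the package provides the
trial-aligned statistics that turn density shifts into phenotype calls:
per-cycle significance tests, stimulus-locked entropy curves, region
time courses, and a bias-corrected mutual-information estimate that
quantifies how strongly the behavior evoked by stimulation depends on
what the fly was doing beforehand.

The supported experimental design is a cohort of single-fly sessions,
each a periodic stimulation protocol — by default 30 cycles of 15 s of
red light followed by 45 s of recovery, filmed at 100 frames per second
as fly-centered grayscale crops — with an experimental arm (able to
respond to light) and a genetically identical control arm (not fed the
chromophore, hence blind to the red light).

# From frames to a behavior space

## Canonicalizing frames

`segment_fly()` outlines the animal with Canny edge detection
(Gaussian blur, Sobel gradients, non-maximum suppression, hysteresis
thresholds at 10% and 30% of the frame's maximum gradient), closes the
outline by morphological dilation (radius 4 px; 3 px leaves gaps at
leg–body junctions for larger flies), fills it, keeps the largest
closed contour, and erodes back by the dilation radius plus one
sub-pixel (diamond) step so the mask tracks the silhouette rather than
its halo. Everything inside the closed curve is fly. Frames with no
contour, or with the fly touching the image border, are flagged invalid
and carried through the pipeline as gaps.

Fly size is normalized per session: `estimate_body_area()` fits a
two-component Gaussian mixture to the foreground intensities of 100
randomly sampled frames — the brighter component is the body (head,
thorax, abdomen), the dimmer one wings and legs — and
`rescale_frame()` applies the uniform scale
`sqrt(reference_area / body_area)`. A degenerate mixture falls back to
Otsu's threshold; a uniform blob counts entirely as body.

Rotational alignment (`align_rotation()`) finds the angle maximizing
the angular cross-correlation of the magnitudes of the two images'
polar Fourier transforms, which is translation-invariant. The polar
grid uses 360 angular bins (1°) and half-image-size radial bins; the
correlation peak is refined by parabolic interpolation. Because the
magnitude spectrum of a real image is 180°-periodic, the alignment is
ambiguous up to a head/tail flip; the package resolves it by choosing
the orientation with more mass on the head side of the fly's own
centroid (synthetic flies are rendered head-up; real data would need an
anatomical prior, which the source videos' rigs typically provide).
`align_translation()` then takes the integer-pixel argmax of the FFT
cross-correlation. Sub-pixel translation is deliberately not attempted:
the downstream features are wavelet amplitudes of PCA mode series and
are insensitive at that scale.

## Radon-transform PCA

Aligned frames are Radon-transformed at 2° spacing (90 projection
angles). The transform is pixel-driven — each pixel's intensity is
split linearly between the two offset bins adjacent to its projection —
so image mass is conserved exactly at every angle, a property the test
suite asserts. Radon-space pixels are then ranked by variance across
the stack and the smallest set capturing 95% of the total variance is
retained (`select_pixels()`); the retained count is data-dependent and
recorded rather than fixed. Plain PCA (mean-centered, no per-pixel
standardization) on the retained pixels keeps the top 50 modes
(`fit_postural_pca()`), and `project_frames()` yields the postural
mode time series. Solvers are exact (LAPACK SVD); requesting more
modes than the numerical rank truncates with a warning.

## Morlet wavelet spectra

`morlet_cwt()` transforms each mode separately with the Morlet
continuous wavelet transform over 25 dyadically spaced channels between
1 and 50 Hz (the Nyquist frequency at 100 fps), keeping only the
amplitudes. The mother wavelet uses nondimensional frequency
`omega0 = 5`; the scale of channel `f` is the exact Morlet relation
`s(f) = (omega0 + sqrt(2 + omega0^2)) / (4 pi f)`, and each channel is
divided by its analytic response to a unit sinusoid at its center
frequency, so a unit-amplitude oscillation yields peak amplitude 1 at
every channel (verified to within 5% by the sinusoid oracle in the
tests). The transform runs over the full-length series by FFT with
mixed-radix zero padding (each channel band-limited to its Gaussian
window, with exact spectral-fold decimation for strided output);
invalid frames are zero-filled and masked
out afterwards. The Morlet envelope at 1 Hz spans roughly a second, so
density changes can precede stimulus onset by up to that smoothing
scale — the reason evoked rises in the trial statistics can appear
slightly before t = 0.

`normalize_spectra()` flattens each frame's mode-by-channel amplitudes,
adds a floor of `1e-12` (keeping later Kullback–Leibler divergences
finite) and normalizes each row to sum to one. All-zero frames become
uniform rows flagged low-power.

## KL-distance t-SNE and re-embedding

Distances between frames are Kullback–Leibler divergences between
their normalized spectra, in bits. Because a full recording is far too
large to embed directly, a training set is distilled hierarchically:
`importance_subsample()` draws 600 exemplars per session with
probability inversely proportional to local density, so rare behaviors
are heavily over-represented; pooled exemplars are then repeatedly
regrouped into blocks of 36,000 and re-subsampled — keeping twice as
many per group as in the previous round — until at most 36,000 points
remain (`hierarchical_training_set()`). Local density is estimated as
a Gaussian kernel sum over the session's pairwise KL divergences with
bandwidth one quarter of the mean divergence. An earlier design
estimated density on a per-session mini t-SNE map, but t-SNE's
density-equalizing layout makes that estimate unreliable exactly when
clusters are tight: on synthetic sessions with a 95%/5% state split the
map-density weights *under*-sampled the rare state, while the
feature-space kernel recovers cluster mass directly and is much
cheaper.

`tsne_embed()` minimizes the exact t-SNE objective over affinities
built from the KL distances: per-point Gaussian kernels calibrated to
perplexity 32 by bisection, symmetrized as `(p_ij + p_ji)/2`. KL
divergence is asymmetric and is used as-is, as the distance fed to the
kernels. The gradient loop (RcppArmadillo) uses the standard schedule:
early exaggeration 12 for the first quarter of 1000 iterations,
momentum 0.5 switching to 0.8, learning rate 200 with adaptive gains;
the converged cost is stored with the full hyperparameter provenance.
All randomness is seeded.

`reembed()` places every remaining frame into the trained map by
minimizing, independently per frame, the same KL-to-Student-t cost
against the training positions, starting from the best-matching
exemplar. Placement affinities use perplexity 5 — each frame is
matched against its handful of nearest exemplars — which makes
re-embedding a left inverse of training: training rows land back on
their trained positions to within 1% of the map extent. Frames failing
the convergence test (gradient norm below `1e-5` and non-increasing
cost over the last ten steps) fall back to the median position of their
10 nearest training rows.

# Map geometry

All densities live on one square grid (`map_grid()`) spanning the
training embedding's bounding box padded by 10%; the full-scale default
is 210 cells per side. `density_map()` is a normalized 2D histogram
convolved with an isotropic Gaussian and renormalized; following the
source conventions, sigma = 1.5 grid cells for map rendering and the
significance analysis and sigma = 2 for entropy curves. Which sigma the
original significance analysis used is not printed anywhere; 1.5 is
this package's recorded choice. `watershed_regions()` segments the
smoothed map into basins around density maxima after zeroing cells
below a background quantile (default 0.75); basins shallower than 1%
of the peak are merged. Distances from a grid cell to a region are
exact Euclidean distance transforms (`region_distance_maps()`).

# Trial-aligned statistics

For fly `i` and cycle `n`, `trial_densities()` builds the mean density
during the first 3 s of stimulation (`rho_on`) and during the 15 s
window farthest from stimulation, t = 30–45 s after onset (`rho_off`).
The off-window follows the quantitative definition in the source
methods; a figure legend describes it as the last 15 s of recovery
(t = 45–60 s), and the window is configurable for readers who prefer
that reading. The per-trial effect statistic is

```
chi[i,n](x, y) = rho_on[i,n] - (rho_off[i,n-1] + rho_off[i,n]) / 2,
```

the stimulation density against the average of the two flanking
reference windows; it is undefined for cycle 1 and sums to zero over
cells by construction.

`significance_maps()` tests every grid cell twice, pooling flies and
cycles as samples: (1) `rho_on` versus `rho_off` within experimental
flies, and (2) experimental versus control `chi`. Both use the
two-sided Wilcoxon rank-sum test — exact for small untied samples,
normal approximation with tie and continuity correction otherwise (the
study conditions give 50+ samples per arm) — and a cell is significant
only if **both** tests pass the Šidák-corrected threshold
`alpha' = 1 - (1 - alpha)^(1/m)`. The comparison count is
`m = ceiling(2^H)` with `H` the Shannon entropy in bits of the mean
experimental density: `2^H` is the effective number of distinguishable
map locations, deliberately an upper bound. `significant_regions()`
takes the connected components of the significant mask; because the
tests are two-sided, cells the fly *vacates* during stimulation also
reach significance, so components are restricted to cells with positive
mean `chi` — activations — before counting `N`. An empty mask
(`N = 0`) is a valid outcome.

`entropy_curve()` pools, for each phase of the 60 s cycle, all
embedded points within ±200 ms (periodic boundaries), forms the phase
density `p_t(x, y)` with sigma = 2, and records its entropy
`H(t) = -sum p log2 p`. The printed formula this implements appears in
the source without the minus sign or a base; standard Shannon entropy
in bits is the only reading consistent with its use in the `2^H`
correction count. Stereotyped evoked behavior shows up as an entropy
drop whose timing tracks the evoked bout; the baseline-subtracted
variant removes the mean over the off-window phases.
`region_timecourse()` reports mean ± sd occupancy of a region over
sliding 3 s windows, and `neuron_average()` averages the positive
significant mean-`chi` maps of several driver lines targeting the same
neuron.

# Context dependence (mutual information)

Each trial is assigned a post-stimulus region: the mode (argmax cell,
ties broken row-major and logged) of its smoothed density over the
first second after onset is matched to the nearest significant region
if the mode lies within or closer than 5 cells to the region's edge —
ties by smaller distance, then smaller region id — and otherwise the
trial receives the 'zero' label (`assign_post_region()`). The
pre-stimulus window is t = −1.5 to −0.5 s; a figure panel mentions
−1.5 to 0.5 s, but a window crossing onset would leak post-stimulus
frames into the "prior" density, so the strictly pre-onset reading is
used everywhere. The mutual information between pre-stimulus density
and post-stimulus region,

```
MI = sum_k p(R_k) * sum_x p_pre(x | R_k) log2[ p_pre(x | R_k) / sum_l p_pre(x | R_l) p(R_l) ],
```

is integrated on the grid (`mutual_information()`); with `N` regions
plus the zero label it is bounded by `log2(N + 1)`. The printed source
formula carries an index typo in its denominator (the bound variable
`l` is unused); the implemented form is the only one that is a mutual
information and respects the source's own `log2(N + 1)` bound.
`partial_mi_map()` returns the cellwise contribution of one region —
the standard pointwise decomposition, which sums to the total exactly;
"partial mutual information" is not defined in the source beyond its
figure, and this decomposition is the package's reading.

The plug-in estimator is biased upward at finite trial counts.
`bias_correct()` recomputes it on bootstrap subsets drawn **with
replacement** at fractions {0.5, 0.625, 0.75, 0.875, 1} of the trials
(100 resamples each) and extrapolates the mean linearly to infinite
trials; the variance is extrapolated the same way. One numerical
subtlety: a with-replacement draw of nominal size `f*n` contains
`n*(1 - exp(-f))` *distinct* trials in expectation, and the
small-sample bias scales with that effective count, not with `f*n`.
Extrapolating against `1/(f*n)` therefore under-corrects — on
label-shuffled data the corrected MI stayed at ~0.08 bits — while the
effective-count abscissa centers the shuffled null on zero. The
subsample schedule and extrapolation order are not printed in the
source; both are recorded here and configurable.

# The synthetic-data generator

Every stage is tested against ground-truthed synthetic sessions
(`synthetic_config()` and friends); no recorded video is required. The
generator emulates the study design: 12-fly sessions (6 experimental,
6 control), 30 cycles of 15 s on / 45 s off at 100 fps, a hidden
behavior-state process, state-specific postural oscillations, LED
stimulation that shifts the state distribution, and optional
dependence of the evoked state on the pre-stimulus state.

* **Latent states** follow a frame-resolution Markov chain: a sticky
  uniform matrix `T_off` (mean dwell 2 s by default — bout-level
  dwell times are approximated through self-transitions) and an
  LED-on matrix `T_on` that adds a per-frame evoked transition
  (default 0.05/frame, i.e. ~0.2 s latency) toward the target state.
  Control flies use `T_on = T_off`. Context coupling `delta` mixes in
  a pull toward `context_map[pre-state]`, the state recorded as the
  LED turns on.
* **Posture modes**: each state owns (mode, frequency, amplitude)
  triples — by default two spectral lines on a dedicated mode pair,
  base frequencies log-spaced over 2–32 Hz — and the mode series is
  the sum of those sinusoids with one random phase per bout plus
  Gaussian noise (sd 0.1, a moderate noise floor relative to the unit
  oscillation amplitudes). Frequencies at or above Nyquist are
  rejected.
* **Rendering** (`render_movie()`) draws a head-up fly (elliptical
  body, head lobe, appendage blobs deflected by the first two modes)
  under a global rigid rotation/translation random walk, flagging
  frames that touch the border. It exists to test frame preparation;
  it is not photorealistic, and mode-level synthesis is the default
  pipeline test path because it keeps full-pipeline tests fast.
* **Embedded-level shortcuts**: `simulate_embedded_fly()` emits map
  coordinates directly (state territories on the unit circle,
  Gaussian scatter 0.05), bypassing rendering and spectral inference,
  for testing the map/statistics/MI stages in isolation.
  `simulate_context_cohort()` additionally draws the pre-stimulus
  state independently per cycle with a deterministic (up to `delta`)
  evoked map — the configuration whose injected mutual information is
  analytic (`context_trial_mi()`). The chain-based oracle
  (`generator_context_mi()`) instead propagates `T_off` backwards
  over the pre-window gap by exact matrix powers (the sticky uniform
  chain is symmetric, hence reversible), accounting for the state
  mixing a realistic chain suffers between the pre-window and onset.
  Two generator modes are needed because a single chain cannot have
  both realistic bout persistence and a low-variance deterministic
  pre-state/label joint at 180 trials.

What passing tests on this generator do **not** show: robustness to
real-video nuisances (lighting drift, occlusion, wing expansion,
off-plane posture), to behaviors without stable spectral signatures,
or to maps whose regions are not well separated. The generator's
states are discrete and spectrally disjoint by construction; real
behavior spaces are continuous and their watershed regions are a
partition of convenience.

# Problem sizes and numerical choices

Tests and the acceptance script run reduced configurations chosen to
exercise every code path at desk scale (`fast_pipeline_config()`):
a 64-cell map grid, a 600-point training set (quota 100 per session),
500 t-SNE iterations, and embedding every 5th–20th frame depending on
the analysis; sessions are 6+6 flies at 10 cycles for phenotyping runs
and 30 cycles (~180 trials) for mutual-information runs. Entropy-curve
flatness checks on null sessions pool both (identical) arms and widen
the pooling half-window to 1 s: at a reduced embedding rate the
±200 ms default leaves so few points per phase that the curve's
sampling noise, not its flatness, dominates. The spec-level defaults
(210-cell grid, 600/36,000 subsampling, full frame rate, ±200 ms)
remain the package defaults.

Other recorded choices: `omega0 = 5` with the exact scale–frequency
relation above; the `1e-12` feature floor; 1° polar bins for rotational
alignment and integer-pixel translation; density-mode ties broken
row-major (and logged); `chi` undefined at cycle 1, which is dropped
from test 2; one shared `m = ceiling(2^H)` for both significance tests;
`0*log(0) := 0` and zero-marginal cells excluded from MI sums;
Wilcoxon exact below 10 per arm (untied), normal approximation with
tie/continuity correction above; linear finite-size extrapolation in
the reciprocal effective trial count.

# Limitations

The package analyzes single animals in fly-centered crops; multi-animal
arenas, identity tracking and background modeling are out of scope, as
are rig control, genetics, and the semantics of human region names
(supported only as a label override). AVI containers are not read
directly — sessions enter as image directories or in-memory arrays.
The head/tail resolver assumes a head-up prior appropriate for the
synthetic renderer. The `2^H` comparison count is intentionally
conservative; with it, weak but real phenotypes will be missed rather
than over-called.
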