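---
title: "ccpalm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ccpalm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it
implements: the forward model behind the simulator, the statistical
model behind each analysis stage, the parameters that matter and their
defaults, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The measurement problem

PALM movies of photoconvertible fluorophores (mEOS2-class labels) show
sparse single molecules that switch on, emit for a few frames, blink
through short dark states, and photobleach. Three systematic effects
stand between the raw movie and cluster-level biology:

* each molecule is detected several times (long on-times and blinking),
  so raw localization counts overcount molecules;
* the stage drifts by hundreds of nanometres over a recording, blurring
  structure well above the localization precision;
* isolated background molecules (autofluorescence, cleaved or
  mistargeted label) contaminate the clustered signal.

The pipeline addresses these in order: detect, localize, de-drift,
merge, filter, and only then measure cluster shape.

## Synthetic data: the stated world

`nerve_cord_layout()` + `build_phantom()` + `simulate_kinetics()` +
`render_movie()` generate movies with known ground truth.

**Spatial model.** Clusters are rotated bivariate Gaussians strung along
a curved cord, plus uniform background molecules
(`background_density`, default 0.15 µm^-2^). Per-cluster content is
lognormal (meanlog 2.3469, sdlog 1.1479), i.e. mean ≈ 20 molecules with
a heavy tail (sd ≈ 33) and roughly 9 of 10 clusters below 50 molecules.
Cluster thickness follows the logarithmic thickness–content relation
characteristic of receptor clusters: FWHM ≈ 26 ln(n) nm with 5 nm
scatter, clamped to [40, 195] nm; length is 1.2–2.8 times the thickness,
capped below 450 nm. The coefficient 26 was fixed by a consistency
requirement, not by fitting any measured outcome: the downstream density
filter (4 neighbors in 50 nm) is, by construction of the analysis,
a filter that *retains* receptor clusters and removes lone molecules, so
a realistic cluster must carry a core density comfortably above that
boundary (≈ 6+ expected neighbors at the core for a 10–20 molecule
cluster). An earlier draft that drew thickness independently of content
produced clusters the filter itself would destroy — a world inconsistent
with the analysis it is meant to exercise.

**Kinetics.** Photoconversion frames are uniform over the movie; this
simulates the *achieved effect* of ramping the activation laser to hold
the conversion rate steady, not the laser power itself. On-times are
geometric (mean `mean_on_frames` = 3 frames); after each on-interval the
molecule re-enters a fluorescent state with probability `p_blink` = 0.3
after an exponential dark time (`blink_dark_mean_s` = 0.5 s), otherwise
it bleaches. The continuous dark times are preserved as an attribute so
their exponentiality can be tested without discretisation artefacts.
Per-emitter photon yields are gamma distributed (mean 480, sd 80
photons/frame), which with the default camera background of 10
photons/pixel puts single-molecule peak signal-to-background-noise
ratios mostly in the 6–8 range.

**Camera.** 107 nm pixels, symmetric Gaussian PSF with σ = 1.8 px,
pixel-*integrated* (difference of normal CDFs, not point-sampled — at
σ = 1.8 px point sampling misallocates a few percent of the flux).
Coordinates are continuous nm with the origin at the centre of pixel
(0,0); pixel *i* spans [i−0.5, i+0.5) pixel widths. Photon shot noise is
Poisson; `noise = "emccd"` adds electron-multiplying excess noise as
gamma-distributed amplification; the test default is plain
Poisson + read noise because no specific camera noise model is part of
the stated analysis. Frame rate (20 Hz) and movie length are
configurable; they are acquisition choices, not constants of the method.

**What the generator does not emulate:** optical aberrations, depth-
dependent PSFs, HILO/TIRF illumination profiles, sCMOS pixel-dependent
noise, 3D structure. A green end-to-end test therefore establishes that
the *analysis chain* is self-consistent for a plausible forward model —
not that any particular instrument is calibrated.

## Detection

The GLRT compares, in a sliding (2h+1)² window (h = ⌈4σ⌉ = 8 px), H1 "a
PSF-shaped spot of fitted amplitude atop a flat background" against H0
"flat background", both with unknown Gaussian noise variance. The
statistic is −2 log Λ = n·log(SSE₀/SSE₁); all window sums are FFT
convolutions, so a frame costs four FFTs. Pixels above the threshold
(default 28, working range 25–30; larger = fewer detections) are grouped
under 8-way adjacency into one candidate per component.

Two open points were decided here: the statistic itself is thresholded
(not a per-pixel p-value), and the default threshold sits at 28 because
at 25 the false-positive rate on pure-noise frames is a few 10^-3^ per
frame, which over a 20,000-frame movie seeds hundreds of one-off fake
molecules, while at 28–30 it is < 10^-3^ with detection probability for
SNR ≥ 6 spots still ≈ 1 (the statistic for such spots is an order of
magnitude above threshold).

## Localization and precision

Each candidate is fitted by least squares with
I(x,y) = A·exp(−((x−x₀)² + (y−y₀)²)/(2s²)) + b, s fixed to the detection
σ (free-σ mode exists for diagnostics; fixing stabilises fits at
SNR ≈ 6). Photons are N = 2π s² A / gain; background noise b is the
robust (MAD) standard deviation of the fit residuals divided by gain —
this is also the denominator of the reported signal-to-noise ratio,
since "intensity-to-noise" has no unique formal definition.

Per-axis precision follows the Thompson form
Δx² = (s² + a²/12)/N + 8π s⁴ b²/(a² N²). The `precision_nm` column
stores the **radial (2D)** uncertainty √(Δx² + Δy²) = √2·Δx, because the
dataset-level "average resolution" quoted for PALM maps of this kind is
a 2D accuracy; `estimate_precision()`/`thompson_precision()` return the
per-axis value. With the default camera and SNR 6–8 spots the mean
radial precision lands in the 20–30 nm band and agrees with the
empirical localization error to within a few percent (the acceptance
suite computes both).

## Drift

Batches of 1000 localizations (the batch size is an analysis choice; the
method only requires "enough structure per batch") are binned into 2D
histograms on a common grid (bin = 100 nm ≈ one pixel). Consecutive
batch images are registered by phase correlation; because localization
histograms are sparse, the normalised cross-power is low-pass filtered
(Gaussian, sd 0.25 of Nyquist) before inversion so the correlation peak
becomes a smooth blob, and the integer peak is refined by a per-axis
3-point Gaussian interpolation (parabolic fallback for non-positive
samples). Relative shifts are accumulated and interpolated with a
polynomial in the frame index (default degree 3, capped at
n_batches − 1), anchored to zero at the first batch midpoint — the
absolute offset is unobservable, only its variation matters. The
estimator uses *all* fitted localizations, dim ones included.

Registration is consecutive-pair only (as described for the original
software), not all-pairs redundant cross-correlation; the latter is more
robust but is a different algorithm.

## Merging

"Same location" is operationalised as "within a capture radius", default
one camera pixel (107 nm): exact coordinate equality is measure-zero
under localization noise, and the 1-pixel radius is the parameterisation
used on commercial instruments alongside an "off gap" of 200 frames.
Consecutive-frame linking matches each localization to the nearest track
whose latest member (frame f−1) is within the radius — linking to the
*last* position, not the track mean, so a slowly wandering spot chains
correctly. The reported molecule position is the precision-weighted
(1/σ²) mean of its members.

Blinking re-linking merges molecules whose spatial separation is within
the capture radius and whose dark gap is ≤ t_d (default 10 s),
transitively, earliest-first, with ties broken by distance then id —
fully deterministic. Temporally *overlapping* molecules never merge:
two emitters visible simultaneously are necessarily distinct. The
implementation uses a spatial hash (cell = capture radius, 5×5
neighbourhood scan) and is effectively linear in molecule count.

The dark-time diagnostic counts unique molecules as a function of t_d
and fits N(t_d) = A·e^(−t_d/τ) + B − C·t_d: the exponential is the
blinking component (τ estimates the dark-state lifetime), the linear
term the slow loss to coincidental same-place conversions. Total
detections are conserved exactly at every merge stage
(Σ n_detections = input localizations); this is asserted in the pipeline
itself.

A practical coupling worth knowing: with t_d = 10 s, two *different*
molecules of one cluster that convert within ~10 s of each other and sit
within one pixel will be merged — an undercounting pressure that grows
with cluster density and shrinks with acquisition length. This is why
the end-to-end validation uses a 20-minute (24,000 frame) acquisition,
squarely in the "few tens of minutes" regime typical of PALM, rather
than a short demo movie.

## Density filter

A point with at least `min_neighbors` = 4 *other* points within
`radius_nm` = 50 (boundary inclusive; a point is not its own neighbor)
is a core point; retained = cores ∪ their in-radius neighbors (the
neighbor rescue keeps the edges of small clusters). The 50 nm value is
canonical; a "0.5 pixel" parameterisation is accepted and converted but
the nm value wins on conflict. The implementation is a cell-list; an
O(n²) brute-force oracle in the test suite checks exact agreement.
Filtering runs after drift correction (neighborhoods are only meaningful
in corrected coordinates). No cluster labels are assigned here — this is
noise removal, not DBSCAN.

## Cluster morphometry

The "2D Gaussian fit" of a contoured cluster is implemented as the
maximum-likelihood Gaussian of the molecule coordinates: centre = mean,
axes and orientation from the eigendecomposition of the 1/n covariance.
For point data this coincides in expectation with an image-domain
least-squares fit but is deterministic, binning-free, and exact in the
noiseless limit. Thickness and length are the FWHMs (2√(2 ln 2)·σ ≈
2.3548σ) of the minor and major axes; θ ∈ [0, π) is the major-axis
direction. Groups below 5 molecules are not fitted (a warning is raised
and the ROI skipped); fitted clusters thinner than the resolution
threshold (default 25 nm, overridable to the dataset's
`mean_resolution`) are flagged `retained = FALSE` and excluded from the
population statistics but counted. Collinear degenerates get σ_min = 0
and are discarded by the same rule.

`propose_rois()` automates the operator's contouring for testability
(grid occupancy → 8-connected components → dilated convex hulls); real
analyses can supply operator-drawn polygons as JSON. Point-in-polygon is
even-odd with boundary points included.

## End-to-end validation: what is compared to what

Ground truth for the phantom run is defined *under the same analysis
rules*: the density filter, ROI proposal and ≥ 5-molecule rule are
applied to the true emitter coordinates, yielding the set of clusters
that are observable in principle; the pipeline's recovered clusters are
compared against that set (count within ±10%, mean content within two
standard errors). This isolates what the test is about — fidelity of
detection, localization and merging — from the filter's intrinsic
selectivity at its detectability boundary, which is identical on both
sides of the comparison.

## Numerical choices and degenerate inputs

* FFT convolutions are circular; a border of one window half-size is
  excluded from detection maps.
* The spot fit rejects centres that leave the window by more than one
  pixel and amplitudes indistinguishable from zero (`fit_ok = FALSE`
  with a reason string); clipped windows at frame edges are never
  fitted.
* Histogram bins and rendering pixels are half-open ([edge, edge+bin)),
  so edge points land deterministically in the higher bin.
* Tables are written with 17 significant digits and round-trip exactly.
* All randomness flows through explicit seeds; identical seeds give
  bit-identical emitter sets, movies, and output tables.

## Known limitations

* Overlapping emitters are not deconvolved; at high activation density
  the detector returns one candidate per merged blob.
* The GLRT uses a Gaussian noise approximation; at very low backgrounds
  (< ~2 photons/pixel) a Poisson-exact test would be more sensitive.
* Drift is 2D only; axial drift is invisible to this estimator.
* Molecule counting inherits the usual PALM caveats (incomplete
  conversion, dark-time coincidences), so contents are best read
  comparatively, not as absolute stoichiometry.
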