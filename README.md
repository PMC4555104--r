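# ccpalm

Single-molecule localization microscopy (PALM) analysis for receptor
cluster morphometry, with a synthetic blinking-emitter movie generator
so the whole chain can be validated without microscope data.

## Who this is for

PALM of photoconvertible labels (e.g. mEOS2-tagged receptors imaged deep
in tissue) produces movies in which sparse single molecules flash on for
a few frames, blink, and bleach. Turning those movies into biology —
"how thick are the receptor clusters, how long, how many molecules do
they hold" — requires a chain of well-defined steps, each with
parameters that matter. This package implements that chain as composable
R functions plus a CLI, and ships a ground-truth simulator so every step
is testable.

## The pipeline

1. **Detection** — per-frame generalized likelihood ratio test (GLRT) of
   a Gaussian PSF (σ = 1.8 px) over local flat background, threshold on
   −2 log Λ (working range 25–30), 8-way-adjacency particle finding.
2. **Localization** — least-squares symmetric 2D Gaussian fit per spot;
   per-localization precision from the Thompson formula
   Δx² = (s² + a²/12)/N + 8π s⁴ b²/(a² N²) with s the PSF sigma (nm),
   a the pixel size (107 nm), N photons, b background noise.
3. **Drift correction** — fiducial-free: localizations are batched
   (1000 per batch), binned into 2D histograms, consecutive batch images
   registered by phase correlation with sub-pixel Gaussian peak fitting,
   cumulative shifts interpolated with a polynomial in the frame index
   and subtracted.
4. **Merging** — detections at the same location (capture radius 1 px)
   in consecutive frames are one molecule; reappearances within a dark
   time t_d ≤ 10 s (200 frames at 20 Hz) are re-linked to absorb mEOS2
   blinking. The dark-time curve N(t_d) = A·exp(−t_d/τ) + B − C·t_d
   separates fast blinking from slow coincidental overlap.
5. **Density filter** — a point with ≥ 4 neighbors within 0.05 µm is a
   core point; core points and their neighbors are retained, lone
   molecules removed.
6. **Cluster morphometry** — each contoured cluster (≥ 5 molecules) is
   fitted with a freely rotating anisotropic 2D Gaussian (uncoupled
   σx/σy); thickness = smaller FWHM, length = larger FWHM
   (FWHM = 2√(2 ln 2)·σ); clusters thinner than the resolution (25 nm)
   are discarded; thickness/length vs content follow y = a·ln(x) + b.

The simulator produces the matching forward model: clusters strung along
a curved nerve-cord path (content lognormal, mean ≈ 20 molecules per
cluster), photoconversion spread uniformly in time, geometric on-times,
exponential short dark times, pixel-integrated PSF rendering, Poisson +
EMCCD noise, and optional stage drift — with the ground truth written
alongside.

## Worked example

```r
library(ccpalm)

lay <- nerve_cord_layout(n_clusters = 6, field_size_nm = c(6848, 6848),
                         background_density = 0.15, seed = 4)
cfg <- palm_config(seed = 4, n_frames = 8000, field_px = c(64, 64),
                   layout = lay, drift_correct = FALSE)
res <- run_pipeline(cfg)
res$log
```

```
              stage n_in n_out                      note
1          simulate  108  8000   emitters in, frames out
2            detect 8000   508 frames in, candidates out
3          localize  508   508             0 fits failed
4 merge_consecutive  508   171
5    merge_blinking  171    76
6    density_filter   76    51
7          clusters   51     4
```

108 true emitters produced 508 raw detections; consecutive-frame linking
and dark-time merging collapse them to 76 molecules (repeated blinking
of one fluorophore is the difference between 508 and 76), the density
filter drops isolated background molecules, and four clusters are
contoured and fitted:

```r
res$cluster_fits[, c("n_molecules", "thickness_nm", "length_nm", "retained")]
```

```
  n_molecules thickness_nm length_nm retained
1           5        28.77     56.65     TRUE
2           9        63.40     97.72     TRUE
3          27        89.07    226.69     TRUE
4          10        45.41     78.22     TRUE
```

Thickness and length are the FWHMs of the rotated Gaussian fitted to
each cluster's molecule coordinates — e.g. the 27-molecule cluster is
89 nm thick and 227 nm long, an elongation of 2.5. The mean localization
precision of the run is printed by:

```r
mean_resolution(res$locs)   # $mean_nm 23.1, $sd_nm 4.6, $n 508
```

which matches the 20–30 nm accuracy expected for spots with
signal-to-noise ratios of 6–8.

## Command line

```sh
Rscript inst/cli/ccpalm.R simulate --out-dir demo --seed 1 --n-frames 2000
Rscript inst/cli/ccpalm.R localize --in demo/stack.txt --out demo/locs.csv
Rscript inst/cli/ccpalm.R merge    --in demo/locs.csv --out demo/mols.csv
Rscript inst/cli/ccpalm.R filter   --in demo/mols.csv --out demo/kept.csv \
        --radius-nm 50 --min-neighbors 4
Rscript inst/cli/ccpalm.R clusters --in demo/kept.csv --out demo/clusters.csv
Rscript inst/cli/ccpalm.R render   --in demo/kept.csv --out demo/image.csv \
        --spot-width-nm 214
```

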