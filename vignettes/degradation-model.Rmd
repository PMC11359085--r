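---
title: "Modelling low-cost infrared cameras and screening thermal recovery curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling low-cost infrared cameras and screening thermal recovery curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmimic)
```

## The problem

Active (dynamic) thermography records how skin re-warms after a brief
cooling stimulus. Each pixel of a registered infrared video yields a
*thermoregulation curve* (TRC) — temperature versus time — and the vascular
changes induced by malignant lesions alter the shape of that recovery.
Screening algorithms built on TRCs have been demonstrated with expensive
research-grade imagers; the question this package addresses is whether a
low-cost microbolometer camera, with its coarser sensitivity (NETD of
50–70 mK instead of ~20 mK), lower frame rate, optical blur, fixed-pattern
noise, ambient-drift sensitivity and shutter-based non-uniformity
correction (NUC), is still good enough.

Rather than running a new clinical study per candidate camera, the package
implements a *degradation model*: characterize the candidate camera's noise
on a blackbody radiator (or from a paired acquisition), then transform video
captured with a high-quality camera so that it looks as if the candidate
camera had acquired it. The screening pipeline can then be evaluated on
original versus degraded data, and the degradation itself can be validated
by mimicking one real camera with another.

Because clinical thermography datasets are private, everything here runs on
a synthetic-scene generator that reproduces the statistical structure the
pipeline relies on.

## The recovery model

Each pixel's TRC is modelled as a double exponential,

$$f(t) = \theta_1 + \theta_2 e^{\theta_3 t} + \theta_4 e^{\theta_5 t},$$

with plateau $\theta_1$ (deg C), amplitudes $\theta_2, \theta_4 < 0$ and
rates $\theta_3, \theta_5 < 0$: after cooling, the curve rises from
$f(0) = \theta_1 + \theta_2 + \theta_4$ toward $\theta_1$ with a fast and a
slow component. `fit_double_exponential()` estimates $\theta$ by nonlinear
least squares with the rates constrained non-positive.

**Numerical choice — variable projection.** For fixed rates the plateau and
amplitudes enter linearly, so the fit solves a linear least-squares problem
inside a Levenberg–Marquardt search over the two rates only. A naive
5-parameter search stalls on noisy curves: as a rate approaches zero its
exponential becomes collinear with the constant plateau term and the
Jacobian degenerates. The projected problem removes that degeneracy; on the
synthetic study conditions every pixel converges. The initializer is
deterministic (time constants at 20 % and 5 % of the record length), with
three deterministic rate-perturbation restarts on non-convergence and a
documented fallback (`converged = FALSE`, mean-level parameters) so a batch
fit never throws.

## The screening pipeline

1. **Registration** (`track_corners()`, `estimate_affine()`,
   `register_cube()`). Four plastic-marker corners are tracked by normalized
   cross-correlation template matching (the first frame's corners are
   supplied, standing in for a manual selection). Consecutive-frame affine
   transforms are composed relative to frame 1 and inverted with bilinear
   resampling; a 3-pixel border is then cropped because residual motion of
   up to three pixels may smear marker temperatures into the edge.
2. **Curve selection** (`fit_cube_trcs()`, `select_trcs()`). The lesion mask
   splits pixels into lesion (L) and non-lesion (N) sets. A reference
   temperature $T_{ref}$ is the mean fitted initial temperature over the
   (converged) lesion fits, and the working set keeps pixels with
   $|f(0) - T_{ref}| \le p \cdot T_{ref}$, default $p = 0.01$. The margin is
   deliberately *relative*; the absolute difference is used even though a
   one-sided rule might be suggested by the selection inequality's printed
   form, because a one-sided rule could never reject pixels that start too
   cold, defeating the purpose of discarding unevenly cooled areas.
3. **Features** (`extract_features()`). From the mean TRCs of the selected
   lesion/non-lesion sets: the sample-normalized Euclidean distance $d$ and
   the energy difference $E_d$ (each curve unbiased by its own minimum
   before taking squared norms; $E_d$ is kept signed, the classifier
   consumes $|E_d|$). From class-descriptive unit-norm model curves
   $f_M, f_B$ (built by averaging fitted parameters over training records of
   each class — averaging parameters keeps the model inside the curve
   family, unlike averaging curves): projection, Pearson correlation and
   distance of each selected pixel's modelled, unit-normalized curve against
   each model, summarized by mean and standard deviation over each area.
   That yields 24 similitude features; the classifier uses the established
   4-vector $[|E_d|, \sigma_{\rho,BL}, \sigma_{proj,BN}, \sigma_{d,MN}]$
   (model class letter first, area letter second).
4. **Evaluation** (`bootstrap_evaluate()`). Records are resampled with
   replacement to the original size, split 80/20, and a classifier (random
   forest by default; KNN, RBF-SVM and XGBoost selectable) is trained on the
   training portion. The descriptive model $f_M, f_B$ is rebuilt inside every
   training fold — building it once on all data would leak test labels into
   the features. Metrics (accuracy, TPR, TNR, PPV, per-subclass TPRs, in
   percent) are accumulated over repetitions and reported as min/max/avg/sd;
   subclass TPRs only over repetitions whose test portion contains that
   subclass, and zero-denominator metrics are reported absent, never as 0.

   One caveat is worth stating plainly: under resampling with replacement a
   test record can also appear in the training portion, so *any* memorizing
   classifier scores far above chance even on permuted labels. Null-
   distribution checks therefore use `bootstrap_config(resample = FALSE)`
   (plain random 80/20 splits), where permuted labels score 50 % as they
   should. The bootstrap protocol itself is unchanged.

## The degradation model

`degrade_cube()` applies four stages in a fixed order — the order matters
and is regression-tested:

1. **Temporal downsampling** to the target frame rate by the nearest-index
   rule: output frame $k'$ is source frame $\mathrm{round}(k' \cdot
   fps_{src} / fps_{tgt})$, no interpolation, so every output frame is a
   real source frame and timing error is at most half a source period.
2. **PSF blur**: each frame is convolved (reflective boundaries) with the
   target camera's normalized point-spread kernel — either measured and
   loaded, or parameterized as a Gaussian of width $\sigma_{psf}$ expanded
   to a $2\lceil 3\sigma \rceil + 1$ kernel.
3. **Spatial noise**: the zero-mean fixed-pattern map $\beta$ measured at
   the blackbody setpoint nearest the scene's mean temperature is added to
   every frame. (The characterization grid spans 15–40 deg C in 5 deg C
   steps; a nearest-setpoint rule is the natural selection policy and is
   logged on use.)
4. **Temporal noise**: per detector, a low-frequency Fourier-series drift
   plus white Gaussian high-frequency noise of per-detector standard
   deviation, synthesized at the target frame rate.

Spatial *downsampling* is off by default: frame dimensions are left
unmodified because resampling would introduce noise that is not
characteristic of the target camera. When enabled (smaller target FPA),
integer block averaging is used and non-divisible margins are cropped.

### Noise characterization

* `extract_spatial_noise()`: average all frames of a blackbody stack
  (temporal noise cancels), subtract the scalar spatial mean; the residual
  is $\beta$, which bundles banding, low/mid/high-frequency pattern and
  non-uniformities. The zero-mean property is an invariant.
* `correct_nuc_jumps()`: NUC shutter events appear as frame-global steps.
  Detection works on the frame-mean series: first differences whose
  deviation from the median difference exceeds 6 times the MAD scale are
  steps (at least 5 frames apart), and cumulative step offsets are
  subtracted from subsequent frames. The median-centering makes a smooth
  warming trend invisible to the detector; the correction is idempotent and
  translation-equivariant. The threshold and gap are parameters
  (`nuc_params()`) because the underlying in-camera logic is unknowable.
* `fit_temporal_noise_series()`: the drift is modelled per detector as a
  Fourier series of order $Z$ (default 3) with fundamental $\omega$ chosen
  by grid search over candidate periods (default 30 s up to the record
  length, 200 grid points); coefficients solve linear least squares at each
  candidate and the residual standard deviation is $\sigma_{HF}$. Because a
  pure grid search quantizes $\omega$, a small residual of the drift leaks
  into $\sigma_{HF}$ when drift amplitudes are much larger than the white
  noise; at the ambient-drift scale characteristic of an air-conditioned
  room (a few tenths of a degree) the leak is negligible. Constant or
  rank-deficient series degrade to a mean-only model with $\sigma_{HF}=0$.
  A shared-frequency fast mode (one $\omega$ per frame) is available; the
  per-detector fit is the default.
* `extract_video_temporal_noise()`: the paired-video mode. Temporal noise is
  the pixel series minus its double-exponential fit, then Fourier-modelled
  as above. Pixels whose recovery fit fails are flagged invalid and excluded
  rather than aborting the run.

### Phase handling

When noise is synthesized from a blackbody characterization
(`mode = "blackbody_profile"`), each detector's drift gets a random phase
offset so mimicked videos do not replay the characterization record
verbatim. In paired-video validation (`mode = "paired_video"`) the fitted
phases are reused, reproducing the actual drift as closely as possible —
whether fitted phases should be reused during mimicry is not decidable from
first principles, so both behaviors exist and the mode selects them.

## The synthetic generator

`generate_acquisition()` draws per-pixel recovery parameters around class
means and low-pass filters the jitter spatially (Gaussian, default 2 px), so
nearby TRCs are highly correlated, as on real skin. The lesion is a disk
whose parameters come from a benign or malignant distribution. Defaults were
chosen once, on physiological grounds, and exposed in
`skin_scene_config()` rather than hard-coded as "true" biology:

* plateaus near 33.5–34.2 deg C, initial temperatures near 29.5 deg C —
  a ~4 deg C cooling deficit recovering over ~1.5 min;
* crucially, the *initial* temperatures of lesion and surround agree within
  about 0.1 deg C (cooling equalizes where every curve starts) while the
  malignant class recovers faster (rate −0.09 versus −0.045 s$^{-1}$ for the
  slow component) toward a slightly warmer plateau — the vascularization
  contrast the features are designed to detect. Keeping $f(0)$ matched is
  also what makes the $p$-margin selection behave as on real data.

`generate_blackbody_stack()` builds a fixed pattern from low-, mid- and
high-spatial-frequency components plus row/column banding (component
amplitudes configurable, zero spatial mean by construction), then adds the
profile's temporal noise per frame; the generating pattern is attached for
oracle tests. `generate_paired_acquisition()` renders one scene through two
camera profiles — same physiology, independent noise draws — and refuses a
"low-quality" camera faster than the high-quality one.
`uniform_temporal_model()` builds generative drift models: one amplitude and
period for all detectors with per-detector random phase jitter around a
common phase and ~10 % amplitude jitter, mimicking how an air-conditioning
cycle is seen slightly differently across a focal plane array. Simulated NUC
jumps are frame-global steps of configurable magnitude and interval with
random sign, matching the step artifacts such cameras produce; per-detector
independent jumps are not simulated.

What the generator does *not* emulate: Pennes-type bioheat physics, 3-D
tumor geometry, motion (scenes are static unless translated explicitly in
registration tests), emissivity variation, and the detailed in-camera NUC
gain logic. Passing tests therefore demonstrate that the pipeline's
statistics, algebra and plumbing behave correctly under the assumed
statistical structure — not that the classifier would achieve any particular
clinical performance.

## Validation experiment

`mimicry_experiment()` reproduces the paired-camera validation end to end on
synthetic data: a 64 × 64, 90 s scene imaged at 50 fps (high quality) and
simultaneously through a low-quality profile; the low-quality video is
NUC-corrected and characterized in paired-video mode; the high-quality video
is degraded with the characterized profile; and the per-pixel Pearson
correlation between actual and mimicked TRCs is reported
(`validate_mimicry()`; zero-variance pixels are excluded and counted).
Two ready-made targets exist: `"lq_noisy"` (15 fps, 70 mK, 0.3 deg C drift
with 60 s period, 1.2 px PSF, 0.5 deg C NUC jumps every 60 s) and
`"lq_quiet"` (8.7 fps, 35 mK, no jumps). These sizes — 4096 pixels, 90 s —
are the package's reference experiment scale; `scripts/acceptance.R` runs
exactly this experiment. Mean correlations on these conditions are printed
by the script rather than quoted here.

## Storage and containers

Acquisitions serialize as a multi-page 32-bit TIFF (temperatures mapped by
the fixed affine transform $(T + 32)/128$ into the sample range, storage
resolution ~3e-8 deg C) with a JSON sidecar (fps, label, subject, marker
corners) and PNG mask/visible images. Writing is aligned to the reader's
quantization grid so repeated write/read cycles are exact after the first.
Camera profiles serialize as YAML with plain-text CSV companions for kernel,
pattern maps and per-detector coefficient planes; loading is deterministic
and re-validates every invariant (normalized PSF, zero-mean $\beta$,
non-negative $\sigma_{HF}$).

## Known limitations

* The Fourier grid search does not polish $\omega$ between grid points;
  extremely large drift amplitudes inflate $\sigma_{HF}$ slightly (see
  above).
* The NUC detector assumes frame-global steps; detector-cluster jumps would
  require a spatial extension.
* Template-matching corner tracking assumes the marker stays visible and
  roughly rigid; scores below 0.5 abort with a tracking-lost error rather
  than guessing.
* Classifier hyper-parameters are defaults (100 trees, k = 5, default RBF);
  tuning is out of scope.
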