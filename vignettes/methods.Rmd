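---
title: "Motion-robust camera-based heart-rate estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-robust camera-based heart-rate estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neopulse)
```

## The measurement problem

Each heartbeat changes the blood volume in facial vessels, which modulates
how the skin absorbs and reflects light. An ordinary RGB camera records
this as a sub-quantization-level periodic color change — remote
photoplethysmography (rPPG). For hospitalized newborns a contact-free
reading is valuable (fragile skin, electrode irritation), but neonates
move: head rotation and non-rigid motion (blinking, grimacing) corrupt
parts of the image and make naive whole-face averaging unreliable.

`neopulse` implements a pipeline built around two ideas:

1. **Divide the face into patches and treat each patch as an independent
   pulse sensor.** Motion artifacts typically cover a minority of the
   face, so most patches still carry a clean pulse.
2. **Fuse the per-patch estimates by histogram majority voting.** At each
   second the patch heart rates are binned; the mean of the fullest bin is
   reported. A corrupted patch votes for an essentially arbitrary rate and
   is statistically unlikely to win.

The stages are: skin segmentation → patch dividing → Eulerian video
magnification (EVM) per patch → green-channel pulse extraction and
sliding-window peak counting → majority voting.

## Stage by stage

### Skin segmentation

The face is found by color, not by facial features — feature-based
trackers tuned on adults fail on neonatal faces, and color is invariant
to the rotations and deformations neonates actually produce. Frames are
converted to HSV, where neonatal skin occupies a compact interval: the
default bounds are lower (0, 10, 60) and upper (20, 150, 255) on the
H ∈ [0, 180), S, V ∈ [0, 255] scale, inclusive at both ends. The binary
mask is then smoothed by a morphological opening (removes skin-colored
specks) followed by closing (fills holes), default 5×5 elliptical
structuring element, and the background is set to black.

Design notes:

* The HSV thresholds are compared on continuous converted values; there
  is no 8-bit re-quantization of the HSV channels, so the bounds behave
  identically across input bit depths.
* The structuring-element size and shape are configurable because no
  single size is canonical; 5×5 is small enough to preserve a neonatal
  face at 640×480 and large enough to delete isolated false positives.
* No largest-connected-component selection is applied. The working
  assumption is that no large skin-colored object other than the face is
  in view; if that assumption fails, segmentation noise enters the patch
  pool (and majority voting is the only remaining defense).

### Patch dividing

Height and width are each cut into *d* equal pieces (sizes differing by
at most one pixel when not divisible; earlier patches take the extra
pixel; row-major order). A patch is kept only if its **first** frame
contains at least one nonzero pixel after background zeroing — a totally
black first frame means the patch holds no region-of-interest
information. First-frame-only validity is deliberate: without head
translation, a patch that sees skin at the start keeps seeing it.

The default is d = 8 (patch size 1/64 of the frame). Smaller grids give
the voting histogram too few entries (d = 2 yields only 4 votes); larger
grids shrink patches to the point where magnification amplifies noise
(in the limit of single-pixel patches the Eulerian view degenerates to
tracking individual pixels). The error curve over d is reproduced on
synthetic data in the acceptance checks; its minimum sits at d = 8.

### Eulerian video magnification

Each patch video is decomposed per frame into a full Laplacian pyramid
(5-tap binomial kernel, replicate borders; detail levels
`max(1, floor(log2(min(H, W))) − 2)`, keeping the coarsest level at least
about 4 px). Every pyramid coefficient's time series is filtered by an
**ideal** (hard-cutoff, FFT-domain) bandpass over the neonatal
heart-rate band 110–160 BPM, i.e. 110/60 ≈ 1.8333 Hz to 160/60 ≈ 2.6667
Hz, the filtered signal is scaled by α = 150 and added back, and the
pyramid is collapsed. For an additive in-band modulation the output
amplitude is exactly (1 + α) times the input; out-of-band content passes
with gain 1. Both gains are verified on synthetic single-tone videos.

Numerical choices:

* The upsampling operator's rows are renormalized at the borders so that
  upsampling preserves constants exactly; consequently a constant image
  has identically zero detail levels and build→collapse is an exact
  inverse (round-trip error is at floating-point level, bound 1e−6 in
  the tests with large margin).
* Amplification is applied per channel in RGB; no chromatic attenuation
  and no wavelength-dependent reduction of α across pyramid levels.
  Because only the green channel is consumed downstream, only green is
  magnified by default (`channels = "g"`); all-channel magnification is
  available.
* Temporal filtering runs once over the whole clip, offline. The hard
  cutoff produces some spectral leakage at the clip edges; the 60 s
  sliding window and the prominence screen in peak detection absorb it.
* Magnified output is kept in floating point (it may leave [0, 255]);
  clipping happens only on video export.

### Pulse extraction

The blood-volume-pulse (BVP) trace of a patch is the per-frame mean of
the magnified green channel over the patch's first-frame skin pixels —
green carries the strongest pulsatile signal, and averaging over skin
pixels only avoids diluting the amplitude by the black background
fraction of edge patches. Peaks are detected on the linearly detrended
trace as local maxima with topographic prominence at least 0.5 trace
standard deviations and minimum separation 0.30 s (80% of the beat
period at the 160 BPM band edge — double counting inside the passband is
impossible; both parameters are configurable as no canonical values
exist). Instantaneous heart rate is the peak count in a 60 s window
sliding by 1 s (count = BPM for a 60 s window; no inter-beat-interval
averaging); windows are indexed by their start second. The ground-truth
pathway applies the identical windowing to reference beat timestamps, so
estimate and reference are compared like for like.

### Majority voting

Votes are binned into left-closed right-open bins aligned at the range
bottom; the default is 5 BPM bins over [100, 170], covering the passband
with margin. The reported value is the arithmetic mean of the modal
bin's members (a bin-midpoint option exists). The bin width is the
single most consequential parameter without a canonical value, hence
prominently configurable. Ties between equally full bins break toward
the previous voted value (heart rate is continuous in time); at the
first instant the lower bin wins. Out-of-range votes are excluded, not
clamped. Seconds with no in-range vote carry the previous value forward
and are flagged in the diagnostics.

### Agreement metrics

With e(i) = He(i) − Hr(i) over N compared seconds: MAE = mean |e|,
MRE = mean |e/Hr| × 100%, RMSE = √(mean e²), and SD = √(mean (e − μ)²)
with μ = mean e — the **population** form (1/N inside the root), as the
metric definitions state. Bland–Altman: bias = μ, 95% limits of
agreement = bias ± 1.96 × SD of differences, defaulting to the same
population convention with a sample-SD (1/(N−1)) option since the
convention for agreement plots is not universal. Paired comparison
requires exact time alignment; there is no interpolation between
mismatched grids.

## The synthetic generator

Clinical recordings cannot be redistributed, so validation runs on
synthetic clips with known ground truth: a skin-colored ellipse
(default RGB (180, 120, 90), HSV (10, 127.5, 180) — inside the skin
bounds) on a mid-blue background, whose face pixels carry an additive
green modulation `pulseAmp · sin(2π · phase(t))`, with the phase
advancing one cycle per beat. Beat times come from integrating the
(possibly time-varying) rate profile; a beat is emitted at each whole
cycle. Defaults mirror the recording conditions the pipeline targets:
640×480 at 30 fps (tests and acceptance checks pass reduced sizes such
as 160×120 explicitly), pulse amplitude 1.5 8-bit units (small enough
that α = 150 magnification is meaningful, large enough that peak
detection is not vacuous), per-pixel Gaussian sensor noise SD 2.
Rendering is in floating point with seeded dither before 8-bit
quantization; identical spec + seed gives bit-identical frames.

Motion models:

* `rotation` — the ellipse spins about its center (head rotation without
  translation; segmentation is color-based, so this mainly exercises
  patch-boundary churn).
* `patch_corruption` — a seeded random fraction of d×d grid cells
  (default d = 8) has its pulsatile term replaced by strong per-cell
  noise (amplitude 40 8-bit units; motion artifacts swing intensities by
  tens of levels, versus the ~1.5-unit pulse). This directly
  parameterizes the assumption the voting scheme relies on: artifacts
  cover whole regions but only a small part of the face.

What the generator does **not** emulate: photorealistic facial texture,
specular highlights, illumination drift, head translation, and
camera-compression artifacts. Passing tests therefore demonstrate that
the pipeline's mechanics are correct and that voting confers the claimed
robustness under the stated artifact model — not clinical-grade accuracy
on real recordings.

## Problem sizes used in tests

The end-to-end checks run 90 s, 30 fps, 160×120 clips through the full
default pipeline (constant rates 120/140/155 BPM clean; 140 BPM with 30%
of grid cells corrupted, compared across d ∈ {1, 2, 8, 10}); module
tests use smaller clips (e.g. 65 s at 60×80). These sizes keep each
full-pipeline run to tens of seconds while leaving every stage —
including pyramid depth ≥ 3 on whole frames — non-degenerate.

## Known limitations

* Whole-frame (d = 1) processing of long clips is the memory-heaviest
  path; the implementation streams the temporal filtering over pixel
  chunks, but very long high-resolution clips should be processed in
  segments.
* The AVI reader/writer handles uncompressed 24-bit RGB only (lossless,
  which is what fixtures and synthetic ground truth require); compressed
  containers must be transcoded externally.
* Head translation violates the first-frame validity assumption; the
  patch pool then contains background-contaminated patches and accuracy
  degrades — this is a property of the method, not of the
  implementation.
* Only heart rate is estimated; no HRV, respiration, or SpO2.
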