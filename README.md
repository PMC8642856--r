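# neopulse

Motion-robust, camera-based heart-rate estimation for hospitalized
newborns (remote photoplethysmography, rPPG).

Each heartbeat causes a sub-quantization-level periodic color change in
facial skin that an ordinary RGB camera records. Neonates cannot wear
adhesive ECG electrodes comfortably, but they also move — head rotation
and non-rigid motion corrupt parts of every frame, so naive whole-face
averaging of the pulse signal is unreliable. `neopulse` implements a
pipeline that divides the face into a grid of patches, recovers a pulse
estimate from each patch independently, and fuses them by histogram
majority voting, so that patches disturbed by motion are out-voted by
the clean majority.

## Method

For a video V at 30 fps:

1. **Skin segmentation** — per frame, pixels with HSV inside
   [0, 10, 60] … [20, 150, 255] (H on 0–180, S/V on 0–255) are kept;
   the mask is smoothed by morphological opening then closing (5×5
   elliptical element) and the background is zeroed.
2. **Patch dividing** — the frame is cut into d × d equal patches
   (default d = 8, patch size 1/64). Patches whose first frame is
   totally black are dropped.
3. **Eulerian video magnification** — per patch: full Laplacian pyramid
   per frame; ideal temporal bandpass of every pyramid position over the
   neonatal heart-rate band 110–160 BPM (1.8333–2.6667 Hz); the filtered
   signal is amplified by α = 150 and added back; the pyramid is
   collapsed. In-band modulations come out with amplitude ×(1 + α).
4. **Pulse extraction** — the blood-volume-pulse trace of a patch is the
   spatial mean of the magnified green channel over its skin pixels;
   peaks are counted in a 60 s window sliding by 1 s, giving one HR
   value (BPM) per second per patch: H_e(i).
5. **Majority voting** — at each second the per-patch HR values are
   binned (5 BPM bins over [100, 170]); the mean of the fullest bin is
   the reported heart rate.

Agreement with a reference series H_r(i) (e.g. ECG-derived beats,
windowed identically) is quantified by MAE, MRE, RMSE and the SD of
error (population form), plus Bland–Altman bias and 95% limits of
agreement (bias ± 1.96 SD of differences).

Because clinical recordings are not redistributable, the package ships a
synthetic-video generator — a skin-colored ellipse with a known additive
green-channel pulse, optional rotation or corruption of a fraction of
grid cells, and exact ground-truth beat times — so the whole pipeline is
verifiable end to end.

## Worked example

```r
library(neopulse)

# a 90 s, 160 x 120, 30 fps synthetic face at 140 BPM with 30% of grid
# cells corrupted by motion-like noise
spec <- syntheticSpec(durationS = 90, fps = 30, height = 120L, width = 160L,
                      hrBpm = 140,
                      motion = list(type = "patch_corruption", fraction = 0.3),
                      seed = 11L)
rv <- renderVideo(spec, returnMasks = FALSE)

res <- runPipeline(rv$video, pipelineConfig(divisions = 8L))
truth <- hrFromBeatTimes(rv$beats, 90)

computeMetrics(res@hr, truth)
#> HR agreement over 31 s:
#>   MAE 0.226 BPM  MRE 0.162%  RMSE 0.475 BPM  SD 0.418 BPM  (mean error 0.226 BPM)

# whole-ROI estimation on the same clip, for comparison
res1 <- runPipeline(rv$video, pipelineConfig(divisions = 1L))
computeMetrics(res1@hr, truth)@mae
#> [1] 4.064516
```

The voted estimate tracks the programmed 140 BPM within a fraction of a
beat per minute, while the whole-face average — which mixes the
corrupted cells into its single trace — is an order of magnitude worse.
That gap is the point of the method.

A command-line wrapper over the same functions lives at
`inst/cli/neopulse.R` (`run`, `metrics` and `synth` subcommands); HR
series are CSV with columns `time_s, hr_bpm`, reference beats CSV with
column `beat_time_s`.

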