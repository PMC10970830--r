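# cytofocus

Frequency-domain sharpness assessment and restoration benchmarking for
cytology images.

## What this is for

Digitising a stained cytology slide is an operator-driven process, and the
commonest capture fault is defocus — the microscope screw set inaccurately,
or focus caught by the background instead of the cells. Whether the
consumer is a pathologist or an instance-segmentation model, blurry
captures cost accuracy, and computational enhancement (super-resolution)
is only worth applying to the images that need it.

`cytofocus` is an R toolkit for the measurement side of that workflow,
aimed at people building or evaluating slide-digitisation QC and
enhancement pipelines:

* a **no-reference sharpness metric**: ring-binned magnitudes of the
  centred 2-D DFT of the luminance plane, scalarised as the
  high-frequency energy fraction;
* **full-reference quality metrics** (PSNR, SSIM with the original
  constants) and per-pair metric tables;
* **degradation simulators** — decimation–bicubic cycles, Gaussian/disk
  defocus, illumination presets — and classical upsamplers
  (nearest/bilinear/bicubic/Lanczos), plus an order-of-operations pipeline
  with a hook for external SR models;
* a calibrated **focus gate** that routes images to pass-through or
  enhancement;
* a COCO-style **instance-segmentation AP evaluator** with percent-change
  accounting against a baseline variant;
* a seeded **synthetic cytology scene generator** with exact ground-truth
  masks, so everything above is testable without microscope data.

## The metric

For a luminance plane *Y*, compute the unnormalised 2-D DFT and shift DC
to the centre. Bin each frequency (u, v) — in per-axis normalised units,
Nyquist 0.5 — by its radius r = sqrt(u² + v²) into ring-shaped masks
(default: 10 equal-width rings spanning [0, r_max]), and record the sum of
|F| per ring. The sharpness score is

    score = (sum of |F| over rings with lower edge >= c) / (total sum of |F|)

with cutoff c = 0.25 (half-Nyquist) by default and the DC ring never
counted. Defocus is a low-pass filter, so blurred captures score an order
of magnitude below sharp ones. PSNR is 10·log10(255²/MSE) in dB; SSIM uses
the 11×11 Gaussian window (σ = 1.5), K1 = 0.01, K2 = 0.03. Percent change
against a baseline b is 100·(x − b)/b, rounded half away from zero to two
decimals, as benchmark tables print it.

## Worked example

```r
library(cytofocus)

# a synthetic stained-aspirate scene and its defocused counterpart
scene   <- generateScene(SceneSpec(shape = c(96, 96), nCells = 6, seed = 1))
blurred <- defocus(scene$image, sigma = 3)

sharpnessScore(luminance(scene$image))   # 0.3594
sharpnessScore(luminance(blurred))       # 0.0434
psnr(scene$image, blurred)               # 25.04 dB
ssim(scene$image, blurred)               # 0.757

# calibrate a focus gate on labelled sharp / defocused images
sharp <- lapply(1:10, function(i)
  generateScene(SceneSpec(shape = c(64, 64), nCells = 4, seed = 40 + i))$image)
blur  <- lapply(sharp, defocus, sigma = 4)
model <- calibrateGate(sharp, blur)
model
#> GateModel v1: enhance iff sharpnessScore < 0.210267 (cutoff 0.25, 10 rings)
#>   calibration: balanced accuracy 1.000 on 10 sharp / 10 blurred

routeImage(blurred, model)$decision      # "enhance"

# percent-change accounting over a published end-to-end benchmark table
evaluateVariants(pipelineBenchmark(), "low quality dataset")
#>                 variant map_50 map_75 map_50_pct_change map_75_pct_change
#> 1  high quality dataset  0.314  0.255             38.94             63.46
#> 2   low quality dataset  0.226  0.156              0.00              0.00
#> 3 subsampling x2, SR x2  0.198  0.120            -12.39            -23.08
#> 4 SR x2, subsampling x2  0.233  0.110              3.10            -29.49
#> 5 subsampling x4, SR x4  0.227  0.155              0.44             -0.64
#> 6 SR x4, subsampling x4  0.279  0.195             23.45             25.00
```

The first two scores say the blurred capture keeps ~4% of its spectral
magnitude above half-Nyquist versus ~36% for the sharp original — the
separation the gate thresholds on. The benchmark table shows the best
enhancement pipeline (SR ×4 before subsampling) recovering +25.00% of
mAP_75 relative to the low-quality baseline, against a +63.46% ceiling
for genuinely high-quality data.

A command-line wrapper with the same functionality ships in
`inst/scripts/cytofocus`:

```sh
Rscript inst/scripts/cytofocus simulate --n-scenes 20 --seed 7 -o outdir
Rscript inst/scripts/cytofocus spectrum outdir/deg/scene001.png --csv rings.csv
Rscript inst/scripts/cytofocus pct --value 0.195 --baseline 0.156   # 25.00%
```

## Package layout

| Area | Files |
|---|---|
| S4 classes and accessors | `R/AllClasses.R`, `R/AllGenerics.R` |
| Image I/O, colour spaces, paired datasets | `R/image_io.R` |
| DFT ring spectrum and sharpness score | `R/ring_spectrum.R` |
| PSNR / SSIM / percent change | `R/quality_metrics.R` |
| Degradations, resamplers, ordered pipelines | `R/degrade_restore.R` |
| Focus gate | `R/focus_gate.R` |
| Instance-mask AP and variant reports | `R/seg_eval.R` |
| Synthetic scenes and paired samples | `R/synth_cyto.R` |
| CLI dispatcher | `R/cli.R` |

The methods vignette (`vignettes/cytofocus-methods.Rmd`) documents the
model, the numerical conventions (grid alignments, kernel truncation,
quantisation policy), the spectral-leakage floor of the windowless DFT
metric and its consequences, and what the synthetic scenes do and do not
emulate.
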