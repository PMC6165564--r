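# actenc

Device-independent low-bit encoding and analysis of actigraphy
(wearable-accelerometer) signals in R.

## The problem

Actigraphs sample gross motor activity at 16 Hz–2 kHz with 6–16 bits per
sample, but the signal itself is spiky and transient: a modest number of
prominent movement events riding on sensor noise and minute vibrations.
For long-term battery-powered monitoring, storing the full device resolution
wastes memory and power. `actenc` implements an acquisition-side chain that
addresses this:

- **normalize** raw device output to physical units per axis (counts-per-g
  division, offset-binary decode onto ±1.5 g, or min–max onto [0, 1]);
- **compound** tri-axial samples into one magnitude channel
  V = √(x² + y² + z²);
- **encode** with a uniform b-bit floor quantizer: with
  Q_f = (2^b − 1)/2, each sample S ∈ [−1, 1] becomes the code
  ⌊S·Q_f + Q_f⌋ ∈ {0, …, 2^b − 1}. The default b = 3 keeps prominent
  movement structure while flooring sub-step amplitudes away — quantization
  doubles as denoising;
- **report** SNR = 20·log10(RMS(S)/RMS(Q_e)), bit rates
  (bits/sample × f_s) and payload space savings;
- **characterize** signals with a KPSS stationarity test, an augmented
  Dickey–Fuller unit-root test, a Kolmogorov–Smirnov Gaussianity test and
  the Gini sparsity index;
- **extract 13 features** (RMS, maxima, peak-to-peak, peak-to-RMS,
  peak-to-average-power, SNDR, three Hjorth parameters, median frequency,
  band power, spiky index, rapid change factor) and **validate** the
  encoding by comparing LDA/linear-SVM classification of raw versus encoded
  feature sets over repeated stratified 70–30 splits, including an
  accuracy-versus-bits sweep.

A seeded synthetic generator emulates three device classes (tri-axial
16-bit 25 Hz sleep actigraphy; tri-axial 6-bit 32 Hz daily-living wrist
data; single-axial 12-bit 2 kHz knee vibration) so the whole pipeline runs
without real recordings.

## Worked example

```r
library(actenc)

cfg  <- synthetic_config("sleep-plm", seed = 1)    # two-class sleep world
m    <- simulate_movement(cfg, "Severe")           # continuous g-values
raw  <- emulate_device(m, cfg$profile)             # 16-bit counts @ 25 Hz
norm <- preprocess(raw)                            # compounded magnitude, g

encode_report(norm, bits = 3)
#> <act_report> sleep, n = 3000, b = 3
#>   SNR raw / encoded :  -102.75 /     6.45 dB
#>   bit rate raw / encoded : 400 / 75 bits/s
#>   space savings : 93.75 %

characterize(norm)
#> <act_characterization> alpha = 0.05
#> Stationarity (KPSS, level)   stat =      1.796  p = 0.01     -> non-stationary
#> Unit root (augmented Dickey-Fuller) stat =     -11.56  p = 0.01     -> no unit root
#> Gaussianity (Kolmogorov-Smirnov) stat =     0.2194  p = < 2.22e-16 -> non-Gaussian
#> Sparsity (Gini index)        stat =     0.5286  p = NA       -> non-sparse
```

Reading the report: the raw 16-bit stream costs 16 × 25 = 400 bits/s; the
3-bit encoded magnitude channel costs 3 × 25 = 75 bits/s, and — counting
all three axes of the raw payload — 93.75% of the stored bits are saved.
The raw-stream SNR is the (strongly negative) scale mismatch between
normalized amplitudes and raw integer codes; the encoded stream's
reconstruction-based SNR is positive. The battery classifies the record as
non-stationary and non-Gaussian, the character typical of real actigraphy.

Raw-versus-encoded validation on a labeled dataset:

```r
d        <- make_labeled_dataset(cfg, n_per_class = 50)
norms    <- lapply(d$signals, preprocess)
raw_set  <- feature_set(norms, d$labels, group = "raw")
enc_set  <- feature_set(lapply(norms, encode_floor, bits = 3),
                        d$labels, group = "encoded")
compare_raw_vs_encoded(raw_set, enc_set, classifiers = "lda",
                       n_seeds = 25, seed = 1)
```

reports mean ± sd accuracy and F1 per group, the encoded-minus-raw gap and
the fraction of seeds where the encoded features do at least as well —
positive under the default world, where the nuisance (noise, slow tonic
drift) sits mostly below the 3-bit quantization step and movement events
above it. `bit_sweep()` runs the same evaluation across bit depths;
accuracy peaks at b = 3.

A command-line interface wrapping these functions is installed at
`system.file("cli", "actenc", package = "actenc")` with subcommands
`simulate`, `encode`, `characterize`, `features`, `validate` and `report`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline from scratch against the installed package: it
simulates each device class, normalizes, 3-bit-encodes and prints the
encoding report for each, runs the raw-versus-encoded classification
comparison on the two-class sleep world, and writes the JSON result
manifest to `--out`. All randomness flows from `--seed`.

## Package layout

- `R/profiles.R`, `R/preprocess.R` — device profiles, normalization,
  vector compounding, CSV reader
- `R/encode.R` — quantization factor, floor encoder, dequantization, SNR,
  bit-rate/space-savings report
- `R/characterize.R` — KPSS, ADF, KS, Gini battery
- `R/features.R` — the 13-feature extractor
- `R/validate.R` — splits, LDA/SVM classification, raw-vs-encoded
  comparison, bit sweep
- `R/simulate.R` — synthetic actigraphy generator and device emulation
- `R/io.R` — bit-packed encoded-signal format (JSON sidecar) and pipeline
  orchestration
- `vignettes/actigraphy-encoding.Rmd` — the model, numerical choices, and
  what the synthetic world does and does not establish
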