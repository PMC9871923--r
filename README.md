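# campariq

Quantification of photoconvertible calcium integrator (CaMPARI-family)
imaging experiments.

CaMPARI-type sensors convert irreversibly from a green to a red fluorescent
state under ~400-nm light, at a rate that grows with intracellular Ca²⁺.
The accumulated **red-to-green ratio (RGR)** of each neuron is therefore a
snapshot of its activity during the illumination epoch, and the same green
channel doubles as a conventional — *negative* — calcium indicator whose
fluorescence dips during activity. `campariq` implements both quantification
arms for two-photon recordings, plus a synthetic two-channel scene generator
with planted ground truth so the whole pipeline can be validated end to end
without microscope data.

## The statistics at the core

Per cell, after subtracting the per-channel dark current (the 0.2 percentile
of all recorded pixels) and the green-to-red bleed-through fraction β
estimated from pre-conversion images:

    RGR = ((red_raw − dark_r) − β · (green_raw − dark_g)) / (green_raw − dark_g)

RGR is pooled by piling cells across fields of view and taking the median.
The photoconversion light dose of an illumination epoch with power *P* (mW),
*n* pulses of duration *t* (s) over a spot of diameter *d* (mm) is

    dose = P · n · t / (π (d/2)²)   [mJ/mm²]

and median RGR versus cumulative dose is fit with a zero-intercept linear
model, slope = Σxy / Σx², with a two-tailed t test on n−1 df. Separation of
stimulated (V1) from reference (S1) populations is measured by the
sensitivity index

    d′ = (x̄_stim − x̄_ref) / √(0.5 (s²_stim + s²_ref)).

For dynamic recordings each trace is bleach-corrected by a divisive
degree-7 polynomial fit; per trial, F_base is the mean of the 0.66 s before
grating onset, F_resp the mean of the lowest 25 % of samples during the 4-s
grating (a dip-seeking statistic — the sensor is a negative indicator), and
ΔF/F₀ = (F_resp − F_base)/F_base. Cells are classified *tuned* by a one-way
ANOVA of the 40 F_base against the 40 F_resp values (p < 0.01) and tuned
cells *oriented* by an ANOVA of F_resp across the 8 drift directions
(p < 0.01).

## Worked example

```r
library(campariq)

pop    <- generatePopulation(120, c(256, 256), seed = 11)
optics <- opticsModel()             # plants 13.1% / 14.6% bleed-through
conv   <- conversionModel(7.9e-4, 0)

# bleed-through from a pre-conversion render
pre     <- renderStack(pop, optics, 1000, power = 1, nFrames = 3, seed = 12)
betaHat <- estimateBleedthrough(extractCellSignals(pre, labelSynthetic(pop)))
betaHat
#> 0.1306

# three 100-mW photoconversion blocks through the full pipeline
lightDose(100, nPulses = 40, pulseS = 1, spotDiameterMm = 7)
#> 103.9379     # mJ/mm^2 per block
sess <- simulatePcSession(seed = 13, nCells = 120,
                          eventDoses = rep(103.9379, 3))
sess$points[, c("event", "cumulative_dose", "median_rgr")]
#>   event cumulative_dose median_rgr
#> 1     1        103.9379 0.08042854
#> 2     2        207.8758 0.16483929
#> 3     3        311.8138 0.24578018

fitDoseResponse(sess$points$cumulative_dose, sess$points$median_rgr)
#> Zero-intercept dose-response fit on 3 points
#>   slope: 0.0007886 per mJ/mm^2 (se 3.25e-06, 95% CI [0.0007746, 0.0008025])
#>   t = 242 on 2 df, two-tailed p = 1.7e-05
```

The estimated bleed-through recovers the planted 13.1 % contamination, the
dose arithmetic reproduces the ~104 mJ/mm² per 100-mW stimulation block
(~208 for the 200-mW protocol), and the fitted slope recovers the planted
7.9 × 10⁻⁴ RGR per dose unit from noisy rendered images.

`runEndToEnd(system.file("extdata", "demo_config.yaml", package =
"campariq"))` runs both arms (after overriding `out_dir`) and writes CSV
tables, JSON reports and a checksummed artifact manifest.

## Package tour

| area | functions |
|---|---|
| synthetic scenes | `generatePopulation`, `applyPhotoconversion`, `renderStack`, `simulateDynamicTraces`, `simulateRegionRgr` |
| ROI extraction | `estimateDarkCurrent`, `extractCellSignals`, `labelSynthetic` |
| photoconversion arm | `estimateBleedthrough`, `computeRgr`, `poolMedianRgr`, `lightDose`, `fitDoseResponse`, `wavelengthRatio`, `normalizedGreenBrightness`, `sensitivityIndex`, `compareGroups` |
| dynamic arm | `correctBleaching`, `segmentTrials`, `computeResponses`, `classifyTuned`, `classifyOriented`, `analyzeDynamicRecording`, `populationSummary` |
| orchestration & I/O | `runEndToEnd`, `simulatePcSession`, `simulateDynamicSession`, TIFF/CSV/JSON readers and writers |

The methods vignette (`vignettes/campariq-methods.Rmd`) documents the model
assumptions, estimator behaviour (including the deliberate bias of the
lowest-quartile response statistic) and every numerical convention.
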