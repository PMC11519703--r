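# gazepipe

Analysis pipelines for comparing **in-lab and webcam-based visual-world
eye tracking** in sentence–picture matching studies, built for the
two-group design used in clinical psycholinguistics: neurotypical controls
versus persons with aphasia (PWA), each tested once with a laboratory
infrared tracker and once with browser-based webcam gaze estimation.

In a visual-world trial, a spoken sentence ("Who is lifted by the
mailman?") plays while a target picture and a reversed-role foil are on
screen. The proportion of gaze samples on the target, time-locked to the
sentence's *disambiguation point*, tracks comprehension in real time. The
methodological question the package addresses: webcam gaze streams are
sparse (~49 ms between samples vs. ~2.3 ms in the lab), spatially noisy,
and temporally *lagged* — can the same analysis recover the same group
effects, and how large is the web delay?

## What the package does

* **Synthetic studies** — `sim_config()` / `simulate_study()` generate a
  complete 65-trial study (15 active, 15 passive, 15 locative, 20 filler;
  target side balanced) for both modalities: lognormal sampling clocks
  moment-matched to the lab (2.3 ms, SD 13.91) and web (49 ms, SD 162.2)
  rates, disambiguation-locked logistic gaze ramps with group-specific
  delay and asymptote, an injectable web lag (default 600 ms), and
  accuracy/RT generation with group × structure effects. Fully seeded,
  byte-reproducible.
* **AOI geometry** — `compute_aois()` builds viewport-proportional
  analysis boxes (x 15–45% and 55–85% of the viewport width; y from 22.5%
  of the height, half a viewport high); `assign_sample()` /
  `label_stream()` classify raw webcam coordinates as target / foil /
  none with a half-open boundary rule, while pre-labeled lab exports pass
  through verbatim.
* **Preprocessing** — per-trial 2-SD timestamp trimming, accuracy +
  per-session 2-SD RT trimming, √RT transform, and half-open 100-ms
  binning of the 0–12,000 ms window into per-trial target-gaze
  proportions (`trim_timestamps()`, `trim_rts()`, `transform_rt()`,
  `bin_gaze()`).
* **Models** — mixed-effects accuracy (binomial) and √RT (Gaussian)
  models via `lme4`/`lmerTest`, and an in-package **weighted quasibinomial
  IRLS** fitter (`fit_binwise()`) for per-bin gaze proportions with
  Pearson-dispersion-scaled standard errors, plus a per-bin contrast
  engine (`binwise_contrasts()`) that turns an omnibus bin-interaction
  model into divergence windows (onset/offset bins).
* **Δgaze lag analysis** — `compute_delta()` forms the per-bin
  control-minus-PWA difference series by structure and modality;
  `fit_delta_model()` regresses it on bin × modality; `estimate_lag()`
  estimates the web-vs-lab delay by peak, dip, or normalized
  cross-correlation.
* **Orchestration** — `run_pipeline()` executes
  simulate → label → trim → bin → model → delta → report, writing every
  intermediate table (CSV), a log with trim percentages, and a manifest
  (config hash, seed, row counts). `inst/cli/gazepipe.R` exposes the same
  stages as shell subcommands.

## Worked example

```r
library(gazepipe)

cfg <- sim_config(n_control = 4, n_pwa = 4, seed = 7)
st  <- simulate_study(cfg)
st
#> <gp_study>
#>   1040 trial rows (8 participants x 2 modalities x 65 trials)
#>   2,850,308 gaze samples

labeled <- label_stream(st$gaze, st$trials, st$viewports)
tr  <- trim_timestamps(labeled)      # removes 0.07% of the eye data
rt  <- trim_rts(st$trials)           # removes 14.2% (inaccurate + outliers)
bins <- bin_gaze(tr$samples, st$trials)

fit_accuracy(st$trials)              # PWA only; controls are at ceiling
#> <gp_fit> binomial-mixed, n = 360
#>               term estimate     se  df statistic         p       d
#>        (Intercept)   1.9577 0.4978 Inf     3.932 8.409e-05  0.4168
#>  structurelocative  -0.8014 0.4352 Inf    -1.841 6.557e-02 -0.1952
#>   structurepassive  -1.3798 0.4290 Inf    -3.216 1.300e-03 -0.3409
#>        modalityweb   0.4387 0.2684 Inf     1.635 1.021e-01  0.1733

pooled <- compute_delta(bins, by_structure = FALSE)
estimate_lag(pooled[pooled$modality == "lab", ],
             pooled[pooled$modality == "web", ], method = "xcorr")
#> <lag_estimate> method = xcorr: lag = 6 bins (600 ms)
#>   peaks: lab bin 28, web bin 40; dips: lab bin 6, web bin 19
```

The accuracy model flags the simulated passive deficit in the aphasia
group (passive coefficient −1.38 log-odds, p ≈ 0.001), and the
cross-correlation of the lab and web Δgaze series recovers the injected
600-ms web delay exactly (6 bins at 100 ms).

A full default-size run (16 + 16 participants, ~11 million gaze samples)
takes a few tens of seconds:

```r
manifest <- run_pipeline(run_config(sim = sim_config(seed = 1),
                                    out_dir = "run1"))
```

See `vignettes/webcam-gaze-comparison.Rmd` for the models, the generator's
assumptions, and every numerical convention (boundary rules, trimming
order, dispersion handling).

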