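# pupilbpr

Model-based correction of blink-locked pupillary responses (BPR) in
continuous pupillometry recordings.

## The problem

Every eye blink is followed by a transient pupil constriction and
re-dilation lasting about three seconds. Because spontaneous blinks
cluster at task "breakpoints" (just after a stimulus or a response),
this blink-locked response is time-locked to the trial structure of
cognitive experiments: it distorts trial-averaged pupil traces,
interacts with baselining, and attenuates condition effects. The
common remedy — deleting and linearly interpolating several seconds
after every blink — throws away genuine signal and can cost a large
fraction of an experiment's statistical power.

`pupilbpr` is for pupillometry researchers who want to *remove the
blink response itself* and keep everything else. It implements:

* blink detection (missing samples, implausibly small sizes, and
  zero-phase high-pass jump detection, merged over 200-ms gaps),
  peri-blink artifact removal with a derivative-based endpoint, and
  0.02–4 Hz zero-phase Butterworth band-passing in second-order
  sections;
* a generative model of 3-s windows on a 16-point grid: a shifted,
  scaled gamma-density kernel `h(x) = γ f(x − t; α, β)` with a
  blink-specific gain `θ_j`, on a Box-Cox-transformed Gaussian
  background with AR(1) covariance `Σ_kl = σ² ρ^|k−l|`;
* staged maximum-likelihood estimation of `{λ, σ, ρ, α, β, γ, t}`
  and all per-blink gains, with overlap handling and an optional
  evoked-response adjustment for task data;
* counterfactual correction (`subtract_bpr()`) and the classic
  linear-interpolation comparator (`interpolate_blinks()`);
* a synthetic-data generator for confounded pupillometry experiments,
  a closed-form blink-rate confound predictor, and an evaluation
  battery (trial classification by blink history, blink-rate time
  courses, response magnitudes, amplitude-quantile profiles, ROC
  discriminability, bootstrap power analysis).

## A worked example

```r
library(pupilbpr)

# a 10-minute synthetic fixation recording: canonical kernel
# (-0.2 mm trough 0.9 s after blink offset), 0.3-Hz blinks,
# gamma-distributed blink-to-blink gains (mean 1, CV 0.6)
run <- synthesize_trace(sim_config_fixation(n_trials = 200, seed = 1))

pp  <- preprocess_trace(run$trace)   # detect, de-artifact, band-pass
fit <- fit_bpr_model(pp$trace, pp$blinks)
fit
#> BPR generative-model fit
#>   segments: 38 blink-free, 166 blink-affected
#>   kernel: alpha=10.146 beta=0.164 s gamma=-0.240 mm t=-0.592 s
#>   kernel trough: -0.192 mm at 0.91 s after blink offset
#>   noise: lambda=1.751 shift=0.785 sigma=0.0511 rho=0.900
#>   amplitudes: n=166, mean theta=0.846 (SD 0.726)

corr <- subtract_bpr(pp$trace, pp$blinks, fit)
```

The printed kernel trough (−0.192 mm at 0.91 s) recovers the
generator's truth (−0.2 mm at 0.9 s) up to the estimation noise of a
single 10-minute run; the correction subtracts each blink's scaled
kernel from the trace and leaves every sample outside the blink
windows untouched. `tidy(fit)` and `glance(fit)` give the parameters
and fit summary as tibbles, `autoplot(fit)` draws the kernel against
the blink-free mean, and `write_bpr_model()` serializes the fit as
JSON.

For task data, pass the trial table so event-locked responses do not
leak into the kernel, then compare correction strategies:

```r
odd <- synthesize_trace(sim_config_oddball(300, seed = 1))
pp  <- preprocess_trace(odd$trace)
fit <- fit_bpr_model(pp$trace, pp$blinks, events = odd$events)
mags <- response_magnitudes(odd$events, subtract_bpr(pp$trace,
                                                     pp$blinks,
                                                     fit)$corrected)
power_bootstrap(mags, oddball_coding(), n_grid = seq(20, 400, 20),
                reps = 10000, seed = 1)
```

See `vignettes/bpr-correction.Rmd` for the model, the estimation
stages, and the design decisions.

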