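---
title: "Classification images from noise-pattern oddity tasks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification images from noise-pattern oddity tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pareidoscope)
```

## The problem this package addresses

Reverse correlation asks what an observer *was looking for*: if choices
among pure-noise stimuli are driven by an internal template, then the
noise patterns the observer selects will, on average, resemble that
template more than the ones it rejects.  The technique is standard with
human participants who can be told "find the face".  With observers who
cannot follow verbal instruction — human infants, non-human primates —
the top-down set has to be induced instead, e.g. by interleaving
target-absent probe trials into a discrimination task the observer has
been trained on, so that a *search image* for the trained category is
active when the probes appear.

`pareidoscope` implements that full design as a simulation-plus-analysis
pipeline:

1. **Stimuli** — 2D Gaussian luminance noise canvases; procedural target
   banks (two face categories drawn as top-heavy eyes-plus-mouth
   layouts, and stroke-glyph letters); alpha compositing of a target
   into the canvas center; an elliptical aperture with a central
   fixation cross for display.
2. **Task** — a three-alternative oddity task: sessions of 48 trials
   (12 easy baseline, 24 difficult baseline, 12 target-absent test
   trials, shuffled), stimuli placed at 3 random cells of a 3 x 2 grid,
   a one-trial correction procedure after baseline errors, and
   noncontingent 50% reward on test trials.
3. **Observers** — template matchers with softmax choice, position
   bias, lapses and evidence-dependent response times.
4. **Analysis** — selected/unselected average images, difference
   (classification) images with luminance enhancement, per-pixel linear
   mixed models with Benjamini-Hochberg FDR control, a random-selection
   null calibration, and the supporting analyses (log-RT mixed model,
   position-bias chi-square, Spearman correlations, RT median split,
   category brightness contrasts, radial Fourier spectra, Euclidean
   image distances).

## The core statistical model

For each test trial the pixel planes of the chosen stimulus and the
pixelwise mean of the two rejected stimuli are recorded.  For every
coordinate of the 200 x 220 area of interest (AOI) centered on the
canvas, luminance is modelled as

$$
y_{ptc} = \beta_0 + \beta_1\,\mathrm{selected}_c + u_p + v_{t(p)} + \varepsilon_{ptc},
$$

with participant random intercepts $u_p$, trial random intercepts
$v_{t(p)}$ (trials are unique within participants, so the trial factor
is automatically nested), and a Gaussian response.  $\beta_1$ is the
selected-minus-unselected contrast; its per-pixel p-values (Satterthwaite)
are corrected by the Benjamini-Hochberg step-up at $q = 0.05$ over all
AOI pixels of one analysis jointly.

### Exact closed form for the paired design (`fast_paired`)

Fitting 44,000 per-pixel mixed models is wasteful, because the design is
perfectly paired: each trial contributes exactly one selected and one
unselected value per pixel.  Writing $d_t = y_{t,\mathrm{sel}} -
y_{t,\mathrm{uns}}$ and $s_t = (y_{t,\mathrm{sel}} +
y_{t,\mathrm{uns}})/2$, the balanced design decomposes into three
independent error strata with expected mean squares

| stratum | df | E(MS) |
|---|---|---|
| pair differences $d_t$ | $n-1$ | $2\sigma_e^2$ |
| $s_t$ within participants | $n-g$ | $\sigma_v^2 + \sigma_e^2/2$ |
| $s_t$ between participants | $g-1$ | $\sigma_v^2 + \sigma_e^2/2 + m\,\sigma_u^2$ |

($n$ trials, $g$ participants, $m = n/g$.)  The REML estimate of
$\beta_1$ is $\bar d$ with $\mathrm{Var}(\hat\beta_1) = 2\sigma_e^2/n$.
When all variance components are interior, $\hat\sigma_e^2$ comes from
the first stratum alone and the Satterthwaite degrees of freedom are
$n-1$ — the familiar paired t-test.  When a component is truncated at
zero (which is the *typical* case at null pixels, because the two
conditions of a trial share no trial effect), REML pools the
corresponding strata into $\hat\sigma_e^2$ and the degrees of freedom
become the pooled total (up to $2n-2$).  `fit_pixel_map(variant =
"fast_paired")` implements exactly this decision tree, vectorized over
pixels; `variant = "group"` fits the same model per pixel through
`lmerTest` and is used for spot verification (the suite checks agreement
to 1e-8 on estimates and 2 significant figures on p-values, including
boundary pixels).  With a single participant the participant stratum
vanishes and the same algebra reproduces the trial-only model used for
individual analyses.

On unbalanced data (participants with unequal trial counts, as after a
median split with odd counts) the stratum decomposition is approximate;
the generic `lmerTest` variants remain available as the exact reference.

Pixels whose per-trial differences have zero variance cannot support the
model; they are flagged singular, their p-value set missing and excluded
from the FDR family — never silently assigned p = 0.

### Enhancement

Average and difference images are rendered for display with
$E(i,j) = (L(i,j) - M)\,\times\,20 + 128$, where $M$ is the mean
luminance of the *entire* image (not the AOI), then rounded half away
from zero and clipped to [0, 255].  For difference images $L$ is the
difference of the raw average planes (difference first, then
enhancement).  Raw real-valued planes are always retained and all
statistics use them; enhanced planes are display artifacts only.

## The synthetic observer

Choice: the observer computes the Pearson correlation $s_k$ between its
template and the AOI pixels of each of the three stimuli and picks
stimulus $k$ with probability
$\mathrm{softmax}_k(\beta s_k + b_{\mathrm{cell}(k)})$, mixed with a
uniform lapse.  Response time is
$\mathrm{rt} = \mathrm{rt}_\mathrm{base} - \mathrm{rt}_\mathrm{slope}\cdot\max_k s_k + \mathcal N(0, \mathrm{rt}_\mathrm{sd})$,
floored at 1 ms.  Both policies are deliberately simple stand-ins for
real decision processes and are pluggable through the `observer()`
interface.

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| noise mean, SD | 128, 30 (8-bit luminance) | mid-gray with clearly visible contrast, the common choice for Gaussian-noise classification images; the task never states these, so they are configuration keys |
| opacity easy / difficult | 0.50 / 0.20 | produces a large accuracy gap in the simulated observer, mirroring the easy-versus-difficult error-rate ordering |
| `beta` | 50 | a near-deterministic template matcher: baseline choices are evidence-driven, as the very low easy-trial error rates require |
| `lapse` | 0.06 | a lapse picks a distractor 2 times in 3, so 0.06 reproduces a ~4% baseline error rate |
| `rt_base`, `rt_slope`, `rt_sd` | 1300 ms, 1200 ms, 150 ms | easy-trial similarities (~0.5) land near 700 ms and test trials near 1300 ms, so log-RT test-versus-easy contrasts fall in the 0.4-0.6 range typical of this task family |
| frame, cross | stroke 2 px, black; cross 12 x 12, arms 2 px | the display spec fixes only the bounding boxes and "black"; noise outside the ellipse is masked to black |

Test fixtures (`make_fixtures()`) use an idealized observer —
`beta = 50`, `lapse = 0` — and a *strongly* evidence-coupled RT
(`rt_sd = 30` ms).  The coupling is deliberate: at fixture scale the
evidence term `rt_slope * sd(max similarity)` is roughly 36 ms, so the
residual SD must sit below it for response times to carry any evidence
signal.  Properties conditional on informative RTs (the median-split
direction) are demonstrated with this observer; with the realistic
150 ms default the same effect exists but is heavily diluted.

## What the generator does and does not emulate

The simulator reproduces the *design*: session composition, grid
placement, correction trials, noncontingent reward, unique noise per
trial, and a top-down template driving target-absent choices.  It does
not emulate photographic targets (targets are procedural drawings),
learning across sessions, motivation or satiety, eye movements, spatial
correlation in the noise (pixels are independent), or inter-individual
template differences unless different observers are supplied.  Passing
tests therefore validate the machinery and its calibration — they do not
certify that real observers behave like softmax template matchers.

## Numerical and design choices

* **Quantization** — all 8-bit planes round half away from zero before
  clipping; the same rule is used everywhere so renderings are
  deterministic.
* **Coordinates** — row-major, row = vertical; AOI offsets count skipped
  pixels (the 200 x 220 AOI sits at offsets col 50, row 65 on the
  300 x 350 canvas).  Exported CSVs use 1-based AOI-local row/col.
* **Grayscale** — stimuli are single-channel; an RGB reading of them
  would have three equal channels, so one luminance plane is recorded.
* **Unselected planes** — the two rejected stimuli enter as their
  pixelwise average, one observation per trial, matching how the data
  are recorded.
* **Correction trials** — exactly one correction trial follows each
  baseline error and is always marked resolved; corrections are excluded
  from every analysis.  This is the simplest rule consistent with the
  procedure's description.
* **Test-trial reward** — an independent Bernoulli(0.5) draw per trial
  (not balanced within session).
* **FDR family** — all AOI pixels of one analysis (one category, one
  variant); separate analyses are corrected separately.
* **Median split** — per participant and category; ties go to the
  faster half (`rt <= median`), and a fully tied group flags a
  degenerate split rather than failing.
* **Position-bias chi-square** — computed on test-trial choices only,
  where no target constrains the choice.
* **Brightness contrasts** — AOI coordinates are the observational
  units; a plain linear model is the default and a row/column
  random-intercept variant is provided, since the appropriate
  random-effect structure for spatially indexed observations is
  genuinely open.  Both report the same contrast on flat inputs.
* **Radial spectra** — mean removal, 2D FFT, integer-rounded radius in
  cycles per image, bin-mean amplitude, profile length
  `floor(min(h, w)/2)`; correlations are taken between log profiles.
* **Log base** — natural log for RT modelling.

## Problem sizes used by the test suite

The suite runs everything at two down-scaled geometries chosen so the
full pipeline stays interactive: *tiny* (30 x 34 canvas, 20 x 22 AOI =
440 pixels, up to 1,200 test trials) and *small* (74 x 83 canvas,
50 x 55 AOI, 100 test trials across 5 participants).  At these sizes the
closed-form map fits in well under a second, the null calibration runs
100 random-selection replicates, and template recovery is strong
(correlations near 0.6 at 300 trials, rising with trial count).  The
full-scale geometry is exercised for design-exactness checks (canvas,
AOI, session composition) and is the default for real use.

## Known limitations

* The closed-form variant assumes Gaussian responses and balanced
  pairing; heavy unbalance should be checked against the `lmerTest`
  variants.
* No spatial inference: pixels are tested marginally and BH-corrected;
  cluster-extent or maxT permutation methods are out of scope.
* The RT model is linear in evidence with Gaussian noise — adequate for
  ordering effects, not for RT distribution shape.
* Enhancement clips: saturated pixels lose magnitude information, which
  is why statistics never touch enhanced planes.
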