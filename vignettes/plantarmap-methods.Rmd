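---
title: "Personalized pixel-wise analysis of plantar pressure images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized pixel-wise analysis of plantar pressure images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Group-level statistics on plantar pressure images assume that patients with
the same complaint share one abnormal loading pattern. When a population is
heterogeneous -- as hallux valgus cohorts demonstrably are -- group tests
wash out, and different studies contradict each other. `plantarmap`
implements the alternative: a *personalized* analysis. Healthy peak plantar
pressures are modelled pixel-by-pixel as a function of demographics; a
patient's measured pressures are then compared against their *own* predicted
baseline, and only statistically defensible departures are highlighted, at
pixel resolution.

The pipeline has four stages:

1. **Preprocessing** -- square-grid resampling, total-mean-pressure
   normalization, peak-image extraction, within-foot averaging, left-foot
   mirroring.
2. **Anatomical correspondence** -- mutual-information rigid registration,
   diffeomorphic demons alignment of footprint silhouettes, and iterative
   groupwise construction of an unbiased template.
3. **Pixel-wise modelling** -- ordinary least squares of peak pressure on
   `[age, sex, weight, height, shoe size, 1]` at every template-silhouette
   pixel, with zero-mean normal residual models.
4. **Single-case inference** -- a Crawford-Howell style t-map of the
   patient's residuals, thresholded by random field theory, summarized into
   anatomical region patterns.

## Preprocessing

A measurement is a video $V(\mathbf{x}, t)$ of pressures (kPa) on the plate
grid. Plate sensors are rectangular (7.62 mm x 5.08 mm on the instrument we
target), so every video is resampled by cubic (Catmull-Rom) interpolation
onto an isotropic 3 mm grid. Negative interpolation overshoot is clamped to
zero: pressures are physical quantities. Border samples replicate the edge
value so a constant field survives resampling exactly.

The **mean pressure image** averages, per pixel, the frames in which the
pixel is loaded:

$$M(\mathbf{x}) = \frac{\sum_t V(\mathbf{x},t)\,\delta[V(\mathbf{x},t) > \tau]}
                        {\sum_t \delta[V(\mathbf{x},t) > \tau]}, \qquad \tau = 5\ \text{kPa}.$$

Dividing every sample by $\sum_\mathbf{x} M(\mathbf{x})$ (the *total mean
pressure*) removes the walking-speed effect on pressure magnitude while
leaving the spatial distribution intact. The **peak pressure image** is
$I(\mathbf{x}) = \max_t \tilde V(\mathbf{x},t)$. Thresholds ($\tau$, and the
5 kPa silhouette cutoff) are defined on the raw kPa scale; when an
already-normalized video is re-thresholded the package rescales the cutoff
by the stored divisor, which also makes normalization idempotent.

Repeated measurements of one foot are rigidly aligned to a seeded randomly
chosen reference and averaged, $\bar I = \frac1K \sum_j T_j \circ I_j$,
which suppresses biological and measurement noise roughly by $\sqrt K$.
Right-foot images are mirrored across the anterior-posterior axis so a
single left-foot model serves both sides (left/right pressures are treated
as independent samples of the same anatomy).

## Registration

**Rigid.** Alignment maximizes histogram-based mutual information (50 bins
per dimension, computed over pixels where either image is nonzero, each
image binned on $[0, \max]$). The optimizer is a (1+1) evolution strategy:
a single parent parameter vector (rotation about the moving image's center
of pressure; two translations), Gaussian mutations whose step sizes grow by
1.05 on success and shrink by 0.98 on failure, starting at (2 deg, 4 mm)
and stopping below (0.1 deg, 0.1 mm) or after 500 iterations. Candidate
scoring warps with bilinear interpolation (the metric is smooth enough);
the final transform is applied with cubic interpolation. Because mutual
information is flat when two footprints do not overlap at all, the search
also starts from the center-of-mass translation; if nothing beats the
identity's score, the identity is returned with `improved = FALSE`.

**Deformable.** Footprint *silhouettes* (pressure > 5 kPa) are aligned with
diffeomorphic demons: per iteration, a force step pulls the warped moving
silhouette toward the fixed one (symmetric-gradient Thirion force on
lightly smoothed masks), the update velocity is Gaussian-smoothed and
exponentiated by scaling-and-squaring (6 squarings) before composition, so
every accepted iterate has strictly positive Jacobian determinant. The
coupling and smoothness weights $\lambda_1 = \lambda_2 = 2$ act through the
update kernel width $\sigma_{\text{fluid}} = 1.5\sqrt{\lambda_2/\lambda_1}$
pixels. We deliberately keep the *accumulated* field's diffusion smoothing
light ($\sigma_{\text{diff}} = 0.3$ px by default): smoothing the total
field at the same 1.5 px width contracts boundary displacements faster than
the force can rebuild them and caps silhouette Dice around 0.95 on 2-px
dilations, whereas the fluid-dominated default reaches 0.97+ while keeping
the field diffeomorphic. Both widths are configuration knobs. The best
iterate by Dice is returned (the identity is a candidate, so Dice never
decreases), and registration quality is reported as Dice plus the minimum
Jacobian rather than any claimed equivalence between $(\lambda_1,
\lambda_2)$ and kernel widths, which the formulation leaves open.

## Groupwise template

Pixel statistics need a coordinate frame that is not biased toward any one
foot. The template is built by the classic iterative scheme: pick a random
initial reference from the cohort (seeded); register the current template,
as moving image, to every cohort image (rigid, then demons on silhouettes);
average the rigid transforms (circular-mean angle, mean affine offset) and
displacement fields (pixel-wise mean); apply the average to the template;
repeat until the template's relative L2 change drops below `tol` (default
1e-3) or `max_iter` (default 10) is reached. Two implementation details
matter:

- The template is always rendered by a *single* resampling of the original
  reference through the accumulated composed map. Re-warping the template
  each iteration compounds interpolation blur, which inflates the
  silhouette and prevents convergence.
- Accepted iterates must not move the template more than the previous one
  did (25% slack for optimizer jitter): the register-average-apply loop is
  a contraction near its fixed point, so a growing step signals it has left
  that regime, and the previous template is kept. Because the rigid
  optimizer is stochastic, the iteration also has a jitter floor (a few
  percent relative L2 on noisy cohorts); `tol` is therefore a target, and
  hitting `max_iter` is reported as a warning with the drift trace
  retained.
- The iterated loop converges the template's *shape*, but a template warped
  from one reference keeps that subject's pressure amplitudes, which is
  itself a reference bias. By default the final template intensities are
  therefore the mean of all cohort images registered into the converged
  frame, followed by the standard unbiasedness correction — resampling the
  average through the negated mean of the image-to-template maps, which
  cancels any residual offset of the frame from the population mean. Two
  rounds are run, since the correction is only as good as the
  registrations that estimate it. This is what makes templates built from
  different random initial references agree to within a few percent, and
  it can be disabled (`intensity_average = FALSE`) to reproduce the bare
  warped-reference scheme.

Template construction from per-foot averages (one image per foot) is the
supported design: averaging first stabilizes the silhouettes that drive the
deformable step.

## Pixel-wise model

With all healthy images aligned to the template, each pixel
$\mathbf{x}$ inside the template silhouette gets an ordinary least squares
fit

$$y(\mathbf{x}) = Z\,\mathbf{b}(\mathbf{x}) + \epsilon(\mathbf{x}),
  \qquad \epsilon(\mathbf{x}) \sim \mathcal N(0, s^2(\mathbf{x})),$$

where the rows of $Z$ are $\mathbf{z}_i = [\text{age}_i, \text{sex}_i,
\text{weight}_i, \text{height}_i, \text{shoe size}_i, 1]$ (sex coded
0 = female, 1 = male; covariates used raw, solved by QR factorization
rather than explicit normal equations). The residual variance uses the
$N - p$ divisor ($p = 6$) by default -- unbiased under the regression
model -- with $N - 1$ available by configuration. Residual vectors are
retained: they feed the normality diagnostics (one-sample Kolmogorov-
Smirnov against $\mathcal N(0, s^2(\mathbf{x}))$ per pixel, Benjamini-
Hochberg FDR across the domain) and the smoothness estimate below. The
model exists only inside the silhouette; outside it, registration leaves
too little signal for the normality assumption to be meaningful.

Prediction for a new demographics vector is $I_{\text{predict}}(\mathbf{x})
= \mathbf{z}_{\text{new}} \cdot \mathbf{b}(\mathbf{x})$, clamped at zero
(count reported) and flagged as extrapolation when
$\mathbf{z}_{\text{new}}$ leaves the training ranges.

## Single-case inference

The patient's aligned peak image minus their prediction gives the residual
map $R(\mathbf{x})$. The default t-statistic is the Crawford-Howell /
DisCo-Z prediction-interval form

$$t(\mathbf{x}) = \frac{R(\mathbf{x})}
  {s(\mathbf{x})\sqrt{1 + \mathbf{z}_{\text{new}}^\top (Z^\top Z)^{-1}
   \mathbf{z}_{\text{new}}}}, \qquad \nu = N - p,$$

the only variant with calibrated single-case type-I behavior: the leverage
term accounts for the uncertainty of the personalized prediction itself.
The naive $R/s$ and the literal $R/(s/\sqrt N)$ readings are selectable for
sensitivity analysis; the literal form inflates t by $\sqrt N$ and is not
recommended for inference.

**Random field theory.** Pixel tests across a smooth map need smoothness-
aware family-wise control. The residual smoothness (FWHM, in pixels) is
estimated from the spatial partial derivatives of the unit-normalized
residual fields; resel counts combine the domain area, its perimeter, and
the FWHM. The critical t solves "expected Euler characteristic = $\alpha$"
using the 2D t-field EC densities (orders 0-2). Testing is two-sided by
default ($\alpha/2$ per tail, $\alpha = 0.05$): both abnormally high and
abnormally low pressures are clinically meaningful. Sub-threshold pixels
are zeroed; 8-connected suprathreshold clusters are reported with sign,
extent, peak t, and a supplementary peak-level corrected p (pixel-level
thresholding gates the result; cluster p-values are informational).
Stationary-field EC densities are an approximation on these small,
plausibly non-stationary lattices; the package discloses this in the QC
output, and its null calibration is checked by simulation rather than
assumed. With fewer than roughly 5 residual degrees of freedom no finite
threshold reaches $\alpha$ (the EC density's tail is too heavy); the
package then returns an infinite threshold with a warning rather than a
spurious one.

**Region patterns.** Surviving clusters are summarized against a five-region
partition of the template silhouette -- heel, midfoot, metatarsal 1,
metatarsals 2-5, toes -- built from fractional foot-length bands (heel
0-31%, midfoot 31-55%, metatarsal band 55-81%, toes 81-100%) with the
medial 36% of the forefoot width assigned to MT1. These follow standard
pedobarographic masking conventions; the proprietary 10-region mask they
emulate is not redistributable, so all fractions are configurable. A
pattern flag needs at least 4 px of cluster-region overlap; MT1 and midfoot
(pes planus) patterns require pressure *increases*, the other regions
accept either sign. An alignment Dice below 0.85 marks the whole analysis
unreliable -- with severe deformity the registration cannot guarantee that
statistics compare corresponding anatomy.

## Synthetic data: what it emulates, and what it does not

Every stage is testable without clinical data through a generator that
renders foot-shaped images as sums of anisotropic Gaussian blobs (heel,
midfoot, MT1-MT5, hallux, lesser toes) inside a smooth outline, with

- per-locus amplitudes *linear* in the demographics (effects applied to
  centred covariates), so the pixel-wise linear model is correctly
  specified and ground-truth coefficient maps exist in closed form;
- additive Gaussian pixel noise, spatially smoothed to FWHM 2 px
  (plate and biomechanical noise are correlated across neighboring
  sensors), truncated at zero -- the truncation skew stays negligible
  because the noise SD (10 kPa) is well below loaded-pixel pressures;
- repeated measurements per foot (default K = 24, the healthy-control
  acquisition design; default cohort size 55) under independent small
  rigid misalignments (up to 5 degrees and 6 mm), and a configurable
  fraction of mirrored right feet;
- injectable abnormalities: a Gaussian-tapered disc that adds
  `magnitude * s(x)` for power studies, with its ground-truth mask.

Passing tests on these cohorts show that the estimation and inference
machinery is correct *under the model's own assumptions*. They do not show
that real feet satisfy those assumptions: real cohorts have per-subject
anatomy (handled only through registration), non-linear demographic
effects, and non-stationary noise. The normality diagnostics exist
precisely because the zero-mean normal residual model must be re-checked on
every real dataset.

## Numerical choices and problem sizes

- Interpolation: cubic for pressures (clamped at zero), nearest for masks,
  bilinear inside optimizer loops and for displacement fields.
- Degenerate inputs: all-zero videos raise an explicit error at
  normalization; $s(\mathbf{x}) = 0$ pixels yield $t = 0$ (zero residual) or
  a capped, flagged $t$; empty silhouettes are errors for registration and
  region building.
- Seeds: every stochastic step (reference draws, optimizer mutations,
  cohort generation) takes a caller seed, and derived child seeds stay
  below $2^{31}$; identically-seeded runs are bit-identical.
- The validation studies run at the design sizes: 50 trials for rigid
  recovery (perturbations to 15 degrees / 15 mm), a 20-foot cohort for
  template stability, the full 55 x 24 design for model recovery, 200
  simulated null patients for family-wise calibration, and 50 runs for
  abnormality power. The end-to-end determinism check uses a reduced
  8 x 2 cohort, which exercises every stage.

## Known limitations

- Silhouette-driven demons ignores intensity structure inside the
  footprint; interior correspondence rests on the rigid stage and the
  blob-like smoothness of pressure images.
- RFT thresholds are approximate at FWHM near 1 px and conservative in the
  calibration regime we simulate; nonparametric (permutation) thresholds
  are out of scope.
- The t-threshold needed for family-wise control at $\alpha = 0.05$ sits
  near $|t| \approx 5$ on these lattices, so single-case sensitivity is
  limited to departures well above 3 residual SDs -- a property of
  pixel-level family-wise control itself, quantified honestly by the power
  study.
- Group-level inference (two-sample SPM between cohorts) and time-resolved
  (video) testing are out of scope.
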