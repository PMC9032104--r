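---
title: "Methods: quantitative phenotyping of zebrafish larvae with larvatox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phenotyping of zebrafish larvae with larvatox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatox)
```

# Overview

`larvatox` implements the complete quantitative analysis used in
myotoxicity/rescue studies on zebrafish larvae: a statin-type toxicant
(lovastatin in the default configuration) disrupts skeletal and cardiac
muscle, and a candidate protectant (L-carnitine) is tested for rescue. Six
readouts are covered, each with the statistical treatment conventional for
its data type:

| Readout | Measurement | Statistics |
|---|---|---|
| trunk birefringence | background-subtracted mean trunk intensity | Welch ANOVA + Games–Howell |
| heart rate | peaks of a smoothed ROI-intensity trace, ×60/duration | Welch ANOVA + Games–Howell |
| chamber contraction | (Cd − Cs)/Cd × 100 from perimeters | Kruskal–Wallis + pairwise Mann–Whitney |
| spontaneous displacement | path length, binned into 4 activity ranges | Kruskal–Wallis + pairwise Mann–Whitney |
| touch-evoked response | 4 ordinal classes from distance + undulation | Kruskal–Wallis + pairwise Mann–Whitney |
| atrogin-1 expression | standard-curve qPCR, rpl13a-normalized A.U. | Student's t-test |

Because raw laboratory recordings are bulky and rarely shared, every input
has a seeded synthetic generator with *analytic* ground truth, so the whole
pipeline is testable end to end without any download.

# The synthetic generators and what they do (and do not) emulate

**Heart videos.** The beating heart is rendered as two anti-aliased
ellipses (atrium and ventricle, fixed aspect ratios 0.80 and 0.75) whose
Ramanujan perimeters oscillate sinusoidally between the configured
diastolic (`Cd`) and systolic (`Cs`) values at the true beat rate, with the
ventricle lagging the atrium by a configurable phase (default 0.15 of a
cycle). The anti-aliased edge is constructed so that the half-maximum
iso-contour is *exactly* the target ellipse, which is what makes perimeter
ground truth analytic. Recordings start 0.3 cycles past diastole — real
footage starts mid-cycle, and a diastolic peak exactly at the first sample
would be invisible to any local-maximum detector. The default 96 × 128 px
frame at 60 fps for 30 s mirrors the emulated assay. What is *not*
emulated: pericardial morphology, blood cells, illumination drift, or
motion of the larva itself; passing tests show signal-processing
correctness, not robustness to those nuisances (the ROI is user-supplied
for the same reason the emulated assay frames the heart manually).

**Swim trajectories.** A correlated random walk (wrapped-normal turning,
sd 0.6 rad) with a burst/glide step-length mixture (20% exponential bursts,
mean 3 units; 80% glides, mean 0.5), confined to the 50 mm dish with a 1 mm
wall margin. Step lengths are rescaled once so the polyline length equals
the target distance; confinement flips the heading (or aims at the centre)
without changing any step length, so the generated path length is exact to
machine precision rather than approximate — the property the displacement
binning tests rely on. Speed profiles and thigmotaxis are not modelled.

**Birefringence images.** A striated band (alternating bright/dim stripes,
default period 10 px) on a dark background; a contiguous lesion multiplies
local intensity by an attenuation factor. The lesion width is snapped to a
whole number of stripe periods so the analytic trunk mean
`((1 − f)·1 + f·attenuation) × (hi + lo)/2` is exact; the realized fraction
is recorded in the ground truth. No optics of polarized light is modelled —
the generator produces the *appearance* the scoring function must quantify,
not its physical origin.

**Dose–mortality and Ct tables.** Deaths are binomial with
`logit(p) = β₀ + β₁·log10(C)` (true LC50 = `10^(−β₀/β₁)`); Ct values follow
`Ct = Ct₁ − log_{1+E}(quantity) + ε` with Gaussian noise. Both are exact
closed-form models, so noiseless inputs are exactly recoverable.

All generators draw randomness through one seeded, state-restoring RNG
wrapper; nothing touches the global RNG state, and a fixed seed reproduces
every artifact bit for bit.

# Cardio analysis choices

**Beat detection.** The emulated workflow counts intensity peaks manually;
an automatic detector needs three parameters, set to physiological
defaults and all overridable: smoothing = centered moving average over
0.1 s; minimum topographic prominence = 20% of the smoothed trace's
amplitude range (relative by default, which makes detection invariant to
affine intensity rescaling); minimum separation = 0.15 s, a 400 bpm
ceiling, generous for larval zebrafish (~120–240 bpm). Heart rate is
`n_peaks × 60/duration`, which for a 30 s recording is exactly the
conventional "double the 30-second count".

**Perimeter estimation.** Naive pixel-edge counting overestimates boundary
length by up to ~27% (a digitized disc) and 8-connected chain codes by up
to ~8%. Instead the frame is lightly blurred (Gaussian, σ = 0.8 px) and
the iso-contour at the segmentation threshold is traced with
`grDevices::contourLines`; the polygon length is a sub-pixel estimate with
<1% error on discs, ellipses and squares in our tests (tolerance asserted:
2%). Segmentation is validated to contain exactly one connected region
(EBImage labelling) — zero or multiple candidate regions abort with a
diagnostic rather than returning a silently wrong perimeter. The mask is
computed from the *blurred* image so single-pixel noise cannot fabricate
regions.

**Systole/diastole selection.** Manual workflows pick frames by eye. Here
the chamber-area time series is tracked per ROI; diastolic frames are area
peaks and systolic frames the minima between consecutive peaks, for three
consecutive cycles (the conventional triplicate). Contraction is
`(Cd − Cs)/Cd × 100` per replicate, averaged. An area-based variant
(`use_area = TRUE`) exists because figure legends in this assay family
sometimes describe contraction via chamber *surface*; the perimeter
formula is the default and the two are not asserted to be equivalent.
`Cs > Cd` is reported as negative contraction with a warning, not an
error: inverted measurements are a real QC signal.

# Locomotion choices

Distance bins follow the standard activity ranges with upper bounds
inclusive — `[0, 0.5]`, `(0.5, 1.5]`, `(1.5, 3]`, `(3, ∞)` cm — read
directly off the range wording ("up to 0.5", "more than 3"), so every
distance lands in exactly one bin. Touch responses use the 20 mm
short/long boundary (20.0 mm inclusive in "no more than 20 mm") plus two
declared choices the assay description leaves open: a movement floor
ε = 1 mm separating true immobility from tracking jitter, and a 5 s
post-stimulus window (escape responses complete well within it); both are
arguments. A missing undulation signal with sub-threshold displacement
resolves to `no_response` with a warning. Centroid tracking is
deliberately minimal — background subtraction, thresholding, largest blob,
linear gap interpolation, rejection above 20% missing frames — because
multi-larva identity tracking is out of scope.

# LC50 and qPCR choices

The headline LC50 comes from ordinary least squares of empirical logits on
log10 concentration — the classical graphical method — with an
Anscombe-type continuity correction `p' = (d + 0.5)/(n + 1)` applied only
at boundary doses (0% or 100% mortality), where the raw logit is infinite.
A maximum-likelihood binomial GLM is reported alongside; on noiseless
logistic data the two agree to numerical precision. Fractional (expected)
death counts are accepted, which is what makes the noiseless case exactly
recoverable.

qPCR quantification is absolute via the dilution-series standard curve:
`Ct = intercept + slope·log10(q)`, efficiency `10^(−1/slope) − 1`
(−3.3219 cycles/decade = perfect doubling = 100%). Ct replicates are
averaged before fitting, with their SD carried as metadata. Target
quantities are normalized to the reference gene (rpl13a in the default
configuration) and scaled so the designated reference group equals exactly
1 A.U. The reference group is a config field and defaults to the
lovastatin group; the A.U. convention varies between studies and the
package does not impose one.

# Statistics layer

Standard tests are the base R implementations (`kruskal.test`,
`wilcox.test`, `t.test`, `oneway.test`, `p.adjust`); re-implementing them
would add nothing but risk. Games–Howell, which has no base implementation,
is authored here: pairwise Welch statistics referred to the
studentized-range distribution (`q = t·√2`, `k` groups,
Welch–Satterthwaite df) via `stats::ptukey`. With two groups it collapses
to the Welch t-test (verified to 1e-6); with equal variances and large
equal n it converges to Tukey HSD; its null family-wise error at
3 × n = 15 is 0.051 over 10,000 simulations. The omnibus "ANOVA" preceding
it is Welch's (variance heterogeneity is the reason Games–Howell exists);
the classical one-way ANOVA is attached for reference.

Pairwise Mann–Whitney uses the exact distribution when the smaller group
has ≤ 8 observations and no ties, the tie-corrected normal approximation
otherwise; exactness is verified against exhaustive enumeration of all
rank assignments for every group-size pair up to 6. No multiplicity
correction is applied by default — mirroring common practice in this assay
family, not endorsing it — and the default is announced loudly via a
message; `p_adjust = "holm"` is one argument away. Alpha defaults to 0.05
everywhere and is configurable.

# The orchestrated experiment and the headline pattern

`run_experiment()` draws per-larva measurements for all seven groups from
the configured effect scenario, runs each stage, and applies the matching
statistics. Group sizes default to the midpoints of the emulated design's
per-assay ranges. The scenario runs at *measurement level*: per-larva
values are drawn directly from the group distributions rather than
rendering one video per larva per replicate, which would cost thousands of
renders per replicate while exercising exactly the code paths already
validated on rendered videos by the cardio tests and
`cardio_video_demo()`. This is a deliberate factorization: image analysis
is validated against rendered ground truth; the statistics layer is
validated against distributional ground truth; the demo ties the two
together on a small scale.

`check_headline_pattern()` scores a run against the scenario's built-in
truth using *effect-bearing comparisons only*: impairment must register as
significant LOV-vs-control differences on every measure; rescue as a
significant rescue-vs-LOV difference on rescued measures; non-rescue as a
persistent rescue-vs-control difference on unrescued measures. Comparisons
whose truth is "no difference" are excluded on purpose: at fixed α a true
null is declared significant ~5% of the time per comparison even by a
flawless pipeline, so requiring accepted nulls would measure the α level,
not pattern recovery. Under the default scenario the full fingerprint
(~26 comparisons) is reproduced in ≥ 95% of seeded replicates; the
shortfall comes almost entirely from the n = 5 contraction contrasts,
where the exact Mann–Whitney test has a hard p-value floor of 2/252.

As a structural nod to experimenter blinding, analysis-stage functions
(trace extraction, peak detection, perimeter measurement, classification)
never receive group labels; labels attach only when tables reach the
statistics layer.

# Problem sizes and numerical notes

The test suite and the acceptance script use these scales, chosen as the
smallest at which each property is meaningfully tested: five 30 s/60 fps
videos for heart-rate recovery (one per rate from 60 to 240 bpm, noise at
10% of the chamber contrast); 500 Monte-Carlo replicates at the design
scale (6 doses × 20 larvae) for LC50 recovery; 1,000 larvae for behaviour
binning; 10,000 null simulations for test calibration; 100 seeded
replicates for scenario fidelity. Degenerate inputs are contracts, not
afterthoughts: flat traces yield zero beats (not an error), all-tied
samples yield H = 0 and p = 1, all-dead/all-alive dose tables and
sub-Nyquist frame rates are rejected with explicit messages, and zero
target distances yield exactly stationary trajectories.

Known limitations: no AVI ingestion (video input is multi-page TIFF or
in-memory arrays); no automatic heart or trunk localization (ROIs are
supplied, as in the manual workflows this emulates); single-larva tracking
only; the generators' contrast parameters are free knobs, not calibrated
to real footage — the arena illumination of real recordings is simply not
specified anywhere this package could faithfully copy it from.
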