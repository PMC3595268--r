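---
title: "Models and methods behind nucleoFRAP"
author: "nucleoFRAP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleoFRAP}
  %\VignetteEncoding{UTF-8}
---

# Overview

nucleoFRAP implements two quantitative microscopy workflows that are
usually carried out ad hoc in spreadsheets or interactive ImageJ
sessions, and makes both reproducible and testable:

1. **FRAP quantification** — turning raw fluorescence-recovery-after-
   photobleaching region traces into corrected, normalized recovery
   curves and per-cell estimates of the mobile fraction $M_f$ and the
   recovery half-time $T_{1/2}$.
2. **Subnuclear intensity quantification** — segmenting nuclei and
   nucleoli from fixed-cell multi-channel images and measuring per-cell
   nucleolar/nucleoplasmic intensity ratios, nucleolar areas and nuclear
   mean intensities, summarized per condition with two-sample t-tests.

Because raw confocal data for this kind of experiment are rarely
deposited, the package ships a synthetic-data generator whose ground
truth is explicit. Every stage of the analysis is validated by parameter
recovery: the simulator produces data with known $M_f$, $T_{1/2}$ or
nucleolar enrichment, and the pipeline must return those values.

# The FRAP model

## Recovery curve

The simulator and the fit both use a single-exponential recovery with an
immobile fraction, parameterized directly by the half-time. With
pre-bleach level $P$, post-bleach depth $d$ (fraction of $P$ remaining
immediately after the bleach), mobile fraction $m$ and half-time $h$,
the ideal bleached-region trace for post-bleach time $t \ge 0$ is

$$R(t) = P\left[d + m(1-d)\left(1 - 2^{-t/h}\right)\right].$$

A single exponential is the minimal model consistent with summarizing a
condition by one $T_{1/2}$; no reaction–diffusion physics, bleach-spot
profile or multi-component exchange is modeled. If a protein's true
recovery is multi-phasic, the fitted $h$ is an effective half-time and
the model-free interpolation estimator (below) is the appropriate
cross-check.

Acquisition itself bleaches the specimen ("monitor bleaching"); both
the bleached-region and whole-nucleus traces are multiplied by
$e^{-\lambda t}$ counted from the first acquired frame. A constant
background is added to all traces and independent homoscedastic
Gaussian noise is added per frame (photon-counting noise is out of
scope). The default acquisition layout is 3 pre-bleach frames and 97
post-bleach frames at 1 s intervals; `nPost` is exposed so the
sensitivity of $T_{1/2}$ to the observation window can be explored
(long-half-time conditions truncated before their plateau fit less
reliably; see *Numerical behavior*).

## Energy accounting and the bleach-spot fraction

The bleach pulse destroys fluorophores; that signal is gone, not
redistributed. The simulated whole-nucleus trace therefore drops at the
bleach by `bleachSpotFraction * P * (1 - d)` and does not recover. The
new parameter `bleachSpotFraction` ($a$, default 0.005) is the fraction
of total nuclear fluorescence destroyed per unit bleach depth —
a small confocal bleach spot relative to the nuclear cross-section.

This constant matters because the acquisition correction divides by the
whole-nucleus trace: the post-bleach drop of the total inflates
corrected post-bleach values by $k = 1/(1 - a(1-d))$, giving a mobile
fraction bias of

$$\hat M_f - m \approx \frac{k\,m(1-d)}{1-k\,d} - m,$$

which at $a = 0.005$, $d = 0.4$ stays below half a percentage point for
all $m$. This is the same small positive bias real FRAP analyses accept
when the bleach spot is small; the package documents it rather than
hiding it, and the recovery tests bound it explicitly.

## Correction and normalization

Processing follows acquisition order:

1. **Background subtraction** — the background-region trace is
   subtracted frame-wise; negative results are clipped at zero with a
   warning.
2. **Acquisition correction** — $roi'(t) = roi(t)\,\bar T_{pre}/T(t)$,
   where $\bar T_{pre}$ is the pre-bleach mean of the whole-nucleus
   trace. Any multiplicative decay shared by the two traces cancels
   exactly (up to the constant pre-bleach decay average, which the next
   step removes).
3. **Normalization** — division by $F_{pre}$, the mean of the
   pre-bleach frames; time is re-zeroed at the first post-bleach frame.

The classic "full double normalization"
$\left(roi(t)/T(t)\right)/\left(\overline{roi/T}\right)_{pre}$ is
available (`doubleNormalization = TRUE`). After pre-bleach
normalization the two forms coincide to second order in the per-frame
decay, so the switch exists for completeness rather than because the
results differ.

$F_{post}$ is the value of the first acquired post-bleach frame, with
no averaging — the earliest available estimate of the bleach floor.
$F_{end}$ averages the terminal plateau window of
$\min(20, \lfloor n_{post}/4 \rfloor)$ frames, never fewer than 3: 20
frames for the standard 97- and 297-frame protocols, while keeping
short test series well defined.

## Estimators

$$M_f = \frac{F_{end} - F_{post}}{F_{pre} - F_{post}}$$

$M_f$ is reported as computed, not clipped to $[0,1]$; noise can push
it slightly above 1 and a value above 1.05 raises a flag, since that
usually indicates a background or correction problem.

$T_{1/2}$ has two estimators:

* **`exp_fit`** (default): least-squares fit of
  $v(t) = F'_{end} - (F'_{end} - F_{post})e^{-t\ln 2/h}$ over the
  post-bleach frames, with $F'_{end}$ and $h$ free and $F_{post}$ fixed
  at the observed first post-bleach value; $T_{1/2} = h$. The fit uses
  Levenberg–Marquardt (minpack.lm) started from the interpolation
  estimate, with $h$ bounded positive.
* **`interpolation`**: the first time the linearly interpolated curve
  crosses $F_{post} + (F_{end}-F_{post})/2$. Model-free; accurate to
  the frame interval.

If the fit fails to converge, the interpolation value is reported with
`converged = FALSE`. On noiseless single-exponential data the two
estimators agree within one frame interval, and the fit recovers $h$
exactly regardless of the bleach-spot inflation factor $k$ (the factor
scales both $F'_{end}-F_{post}$ and the curve, leaving $h$ untouched).

# The fixed-cell image model

The simulated field is deliberately simple: non-overlapping nuclear
disks that never touch the border, each containing non-overlapping
nucleolar disks; a DNA channel (uniform nuclei), a nucleolar-marker
channel (uniform nucleoli) and a target channel whose nucleolar pixels
are `trueRatio` times the nucleoplasmic level. Gaussian blur
(default $\sigma = 1$ px, a stand-in for the PSF) and additive Gaussian
noise (default 2% of the nucleoplasmic level) are applied per channel.
Placement uses bounded rejection sampling and errors out when the
requested geometry cannot be packed.

What this emulates well: compartment contrast, optical mixing at
boundaries, detection noise, per-cell sampling variability. What it
does not emulate: clumped or touching nuclei (no watershed splitting is
implemented), intensity gradients and vignetting, textured chromatin
or nucleoli, autofluorescence, and cell-to-cell staining variability
beyond what noise induces. Passing the recovery tests therefore shows
the measurement chain is unbiased under ideal-but-noisy geometry, not
that segmentation will be equally accurate on crowded real fields.

## Segmentation

* Nuclei: Gaussian smoothing (default $\sigma = 1$ px) → global Otsu
  threshold → hole filling → removal of components smaller than 200 px
  and of border-touching components → 8-connected labeling.
* Nucleoli: per-nucleus Otsu threshold computed from that nucleus'
  marker pixels only (robust to per-cell staining variation),
  components under 10 px removed, pixels outside nuclei excluded. The
  nucleolar mask always comes from the marker channel, never from the
  target channel being quantified, so segmentation errors cannot be
  correlated with the measured signal. A nucleus whose marker signal is
  too uniform to threshold is flagged and simply contributes no
  nucleolar pixels.

Thresholding uses an in-package histogram Otsu (256 bins) that accepts
arbitrary pixel subsets; it is verified in the tests against an
exhaustive search over all candidate splits. Connectivity is
8-connected throughout. Pixels are 0-based, row-major, and binary: a
pixel is in a mask or not, with no sub-pixel weighting.

## Measurement and the boundary rim

Per cell, the nucleolar mean is the mean target intensity over the
cell's nucleolar pixels and the nucleoplasmic mean over the nuclear
pixels minus the nucleolar pixels; the ratio is their quotient. The
field background (median intensity outside all nuclei) is subtracted
from both by default, which makes the ratio exactly invariant under
multiplicative rescaling of the channel.

One measured bias is corrected deliberately: blur mixes the pixels at
the nucleus/background boundary with the (dark) outside, so a naive
mean over the full DNA mask underestimates the nucleoplasm by ~3% at
the default optics and a true ratio of 1 is recovered as ~1.03.
Intensity means are therefore taken over rim-eroded masks — 2 px
(about twice the PSF sigma) at the nuclear boundary, 1 px at the
nucleolar boundary, falling back to the full mask when erosion would
empty it. Areas, the mask partition and overlap metrics always use the
full masks; `edgeErode = 0` restores naive means. With the rim
excluded, a ratio of 1 is recovered to within 0.003 and the
enrichment grid 1–5 to within 8% at default optics (exactly, absent
blur and noise).

Because the claimed mask "overlap" of co-staining experiments is
ambiguous, `maskOverlap()` reports all three candidate metrics
($|A\cap B|/|A|$, $|A\cap B|/|B|$, Jaccard) instead of guessing one.

# Statistics

Condition summaries report mean, sample SD (denominator $n-1$) and N.
Comparisons use the pooled-variance two-sample t-test with
$df = n_a + n_b - 2$ and two-tailed p-values (Welch's variant by flag),
annotated with stars at strict thresholds: `*` p < 0.05, `**` p < 0.01,
`***` p < 0.001. The unit of analysis is the cell, pooled across
fields; a per-field aggregation can be done by summarizing the
measurement table first. **No multiple-testing correction is applied**
— each comparison is reported at its nominal p-value, so families of
many comparisons should be interpreted accordingly.

# Numerical behavior and test design

* All generators take an explicit integer seed and hold no global
  random state; identical seeds give bit-identical outputs.
* Noiseless pipeline recovery is verified over
  $m \in \{0, 0.25, 0.5, 0.75, 0.89, 1\} \times h \in \{1, 3, 4.3, 7.6, 10\}$ s
  to $|\Delta m| < 0.01$ and $|\Delta h|/h < 0.02$. $h$ is
  unidentifiable at $m = 0$ and is not checked there. When
  $h > n_{post}\,\Delta t/5$ the plateau is truncated and half-time
  recovery degrades; the free-plateau fit tolerates the default grids,
  but strongly truncated series should be read with that bias in mind.
* Estimates are invariant to monitor bleach rates up to 0.01/s
  (noiseless, within 0.01) and to any positive intensity rescaling.
* Type-I error of the downstream t-test is calibrated by 200 replicate
  null experiments (identical ground truths in both conditions) run
  through the full image pipeline on 160×160 px fields with 5 cells per
  field; the detection power check uses 140 cells per condition as 14
  fields of 10 cells at 256×256 px. These sizes keep the simulations
  statistically meaningful while staying cheap; the measurement chain
  is size-invariant, so small fields are representative.
* Degenerate inputs fail loudly and specifically: invalid ground-truth
  parameters name the offending field, a non-positive whole-nucleus
  trace names the frame, blank images raise segmentation errors,
  infeasible geometry raises a generation error after bounded retries,
  and $F_{pre} \le F_{post}$ makes the mobile fraction an explicit
  error rather than a silent negative value.

# Worked example

```r
library(nucleoFRAP)

## FRAP: recover a known mobile fraction and half-time
truth <- FrapGroundTruth(seed = 1, mobileFraction = 0.89, halfTime = 4.3,
                         monitorBleachRate = 0.002)
est <- analyzeFrap(generateFrapSeries(truth))
mobileFraction(est)   # ~0.894
halfTimeS(est)        # 4.3

## fixed-cell: recover a known nucleolar enrichment
field <- generateNucleiImage(ImageGroundTruth(seed = 21, trueRatio = 2.5))
q <- quantifyField(field$channels)
median(q$measurements$ratio)  # ~2.41

## two conditions, summarized
ctrl <- ImageGroundTruth(seed = 100, trueRatio = 2.0)
trt  <- ImageGroundTruth(seed = 200, trueRatio = 1.2)
ex <- generateTwoConditionExperiment(ctrl, trt, fieldsPerCondition = 2)
meas <- do.call(rbind, lapply(names(ex$fields), function(id) {
    m <- quantifyField(ex$fields[[id]]$channels)$measurements
    m$condition <- ex$manifest$condition[ex$manifest$field_id == id]
    m
}))
summarizeGroups(meas, "ratio")
```

# Known limitations

* FRAP: one-component exponential only; no diffusion coefficients, no
  bleach-spot-profile modeling, no two-phase fits.
* Images: 2-D disks only; no watershed for touching nuclei; nucleolar
  segmentation assumes a usable marker channel; hue/brightness gating
  of transfected cells is not implemented (use an `include` column in
  the manifest instead).
* Statistics: no hierarchical modeling of experiment/field nesting;
  pooling cells across fields slightly understates between-experiment
  variance when fields differ systematically.
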