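# nucleoFRAP

Quantitative analysis of nucleolar protein dynamics from two kinds of
microscopy experiment, with a synthetic ground-truth generator that
makes every stage verifiable by parameter recovery.

**Who it is for.** Cell biologists quantifying (a) FRAP
(fluorescence recovery after photobleaching) of nucleolar or
nucleoplasmic proteins — e.g. nucleophosmin/NPM exchange at the
nucleolus under stress or proteasome inhibition — and (b) fixed-cell
immunofluorescence where a protein's partitioning between nucleolus
and nucleoplasm is measured per cell from multi-channel images.

## What it computes

**FRAP.** Raw per-frame region traces (bleached nucleolus, whole
nucleus, background) are background-subtracted, corrected for
acquisition (monitor) photobleaching using the whole-nucleus trace
(`roi'(t) = roi(t) · T̄_pre / T(t)`), and normalized to the pre-bleach
mean. Per cell the pipeline reports the mobile fraction

    M_f = (F_end − F_post) / (F_pre − F_post)

with F_pre the mean of the pre-bleach scans, F_post the first
post-bleach value and F_end the terminal plateau mean (last 20 scans
for standard protocols), and the recovery half-time T_1/2 from a
least-squares fit of

    v(t) = F'_end − (F'_end − F_post) · exp(−t ln2 / h)

(or a model-free half-recovery interpolation as cross-check).

**Fixed-cell images.** Nuclei are segmented from a DNA counterstain
(Otsu), nucleoli from a dedicated marker channel with per-nucleus
thresholds; per cell the package reports the nucleolar mean, the
nucleoplasmic mean (nuclear minus nucleolar area), their ratio,
nucleolar area and nuclear mean intensity, and aggregates conditions
with pooled-variance two-tailed t-tests and significance stars
(\*p<0.05, \*\*p<0.01, \*\*\*p<0.001).

**Synthetic data.** `FrapGroundTruth` / `ImageGroundTruth` describe
simulated acquisitions with known mobile fraction, half-time,
monitor-bleach rate, noise, and nucleolar enrichment; generators
render region traces, image stacks and multi-channel fields that the
same pipeline can consume, so recovery of the generating parameters is
a complete end-to-end test.

## Worked example

```r
library(nucleoFRAP)

truth <- FrapGroundTruth(seed = 1, mobileFraction = 0.89, halfTime = 4.3,
                         monitorBleachRate = 0.002)
est <- analyzeFrap(generateFrapSeries(truth))
est
#> FrapEstimate: M_f = 0.8945 , T_1/2 = 4.3 s [ exp_fit ]
```

The generated series had a true mobile fraction of 0.89 and half-time
4.3 s; the pipeline recovers 0.8945 and 4.3 s. The small upward offset
in M_f is the documented bleach-spot effect: the bleach destroys a
little of the total nuclear signal, so the acquisition correction
slightly inflates post-bleach values (see the methods vignette).

```r
field <- generateNucleiImage(ImageGroundTruth(seed = 21, trueRatio = 2.5))
q <- quantifyField(field$channels)
median(q$measurements$ratio)
#> [1] 2.415094
head(q$measurements, 3)
#>   cell_id nucleolar_mean nucleoplasmic_mean    ratio nucleolar_area_px ...
#> 1       1       247.6906           102.5504 2.415306               400
#> 2       2       247.7789           102.3879 2.420001               403
```

Twenty simulated nuclei with a true nucleolar enrichment of 2.5 under
1 px blur and 2% noise are recovered with a median ratio of 2.42
(boundary blur accounts for the remaining ~3%).

A thin command-line front end over the same functions lives at
`inst/cli/nucleofrap.R` (subcommands `simulate-frap`, `simulate-image`,
`analyze-frap`, `quantify-image`, `compare`).

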