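---
title: "Methods: multi-level test–retest reliability of CBF maps and pain ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level test-retest reliability of CBF maps and pain ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(aslrel)
```

## The problem

Arterial spin labelling (ASL) measures cerebral blood flow (CBF) in
physiological units without contrast agents, which makes it attractive for
studying *on-going* pain states — e.g. the post-surgical pain that follows a
third molar extraction — where there is no event to time-lock to. Before
such perfusion endpoints can support longitudinal or pharmacological
studies, their test–retest reliability must be quantified, and compared
with the behavioural gold standard, the 0–100 mm visual analogue scale
(VAS).

`aslrel` implements that reliability analysis as a reusable pipeline. The
design it models has sixteen subjects, each scanned in two pre-surgical
sessions (S2, S4) and two post-surgical sessions (S3, S5; one per extracted
side, order counterbalanced), with six perfusion scans per session and
concurrent VAS pain/alertness ratings after every scan. Reliability is
assessed at three levels — inter-subject, inter-session (within-subject)
and intra-session (scan-to-scan) — for the pre- and post-surgical states
and for the change in CBF (ΔCBF) between them.

## The reliability statistic

Everything rests on the consistency intraclass correlation for a two-way
layout with fixed raters, computed from the mean squares of the complete
targets × raters table:

$$\mathrm{ICC}(3,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS}$$

where $BMS$ is the between-targets mean square, $EMS$ the residual mean
square and $k$ the number of repeated measurements. Being a consistency
coefficient, it ignores the rater main effect: adding a constant to one
repeat leaves it unchanged. Negative estimates are reported unclamped
(truncation would bias the simulation-recovery checks), and all-constant
tables return an explicit *undefined* result rather than a number.
Qualitative bands follow the conventional cut points — below 0.4 poor,
[0.4, 0.6) fair, [0.6, 0.75) good, 0.75 and above excellent. The published
ranges leave gaps at 0.59–0.60 and 0.74–0.75; half-open intervals are used
so every value maps to exactly one band. Confidence intervals for the ICC
are deliberately out of scope.

Two companions appear in the output tables: the coefficient of variation
(sample SD over mean, undefined at zero mean) and the standard error of
measurement. The SEM column of the intra-session table is not given a
formula in the reliability literature we mirror, so the package documents
its own choice, the standard psychometric definition
$\mathrm{SEM} = s_\text{pooled}\sqrt{1-\mathrm{ICC}}$, without asserting it
is the only one.

## The generative model

Because the original scan data are not deposited, a synthetic-data module
defines the study conditions. The CBF value of subject $i$, session $s$,
scan $t$ at voxel $v$ is

$$y_{istv} = \mu + b_{iv} + (\delta + g_{iv})\,[s\ \text{post}]\,[v \in \text{network}]
  + \varepsilon^{(s)}_{isv} + \varepsilon^{(w)}_{istv}$$

with $b \sim N(0,\sigma_b^2)$ a stable per-subject baseline,
$g \sim N(0,\sigma_g^2)$ the subject's pain-response magnitude (constant
across both post-surgical sessions — without it, ΔCBF would have no
between-subject signal at all), $\varepsilon^{(s)} \sim N(0,\sigma_s^2)$ a
session effect *shared by all scans of the session*, and
$\varepsilon^{(w)} \sim N(0,\sigma_w^2)$ i.i.d. scan noise. All effects are
drawn independently per voxel: the "once per (subject, session)" structure
of the session effect refers to time (shared across the six scans), not
space. This per-voxel interpretation is what gives the intra-voxel ICC
(ICC$_v$, voxels as targets) its between-voxel variance; spatially constant
noise would make every ICC$_v$ degenerate. No spatial autocorrelation is
modelled, nor ASL noise physics (label decay, motion); passing tests
therefore demonstrate estimator correctness and calibration, not robustness
to structured imaging artefacts.

Defaults (CBF in ml/100 g/min): grand mean 50, $\sigma_b^2 = 25$,
$\sigma_s^2 = 9$, $\sigma_g^2 = 4$, $\sigma_w^2 = 4$, $\delta = 10$. The
session variance deliberately exceeds the scan variance: week-scale
physiological drift between visits is larger than within-session drift when
the subject is not repositioned, and it is exactly this regime that makes
intra-session reliability exceed inter-session reliability. VAS defaults:
pain mean 60 mm (safely above the 30 mm scanning criterion) with
subject/session/scan SDs of 15/5/3 mm; alertness mean 70 mm with SDs
10/5/3 mm. Ratings are clipped to the bounded 0–100 mm scale (the clipped
count is attached to the table) and, by default, pre-surgical pain is
exactly zero — the floor effect. The left/right surgery order is recorded
per subject but has no effect on generated values, mirroring the absence of
a side effect in the modelled study.

## Closed-form expected ICCs — the oracle chain

With scan noise folded into an effective session error
$\sigma_e^2 = \sigma_s^2 + \sigma_w^2/m$ ($m$ scans per session), the
expected consistency ICC at a network voxel has a closed form at every
analysis level:

| level | expected ICC |
|---|---|
| pre state (S2 vs S4) | $\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$ |
| post state (S3 vs S5) | $(\sigma_b^2+\sigma_g^2)/(\sigma_b^2+\sigma_g^2+\sigma_e^2)$ |
| ΔCBF, paired baselines | $\sigma_g^2 / (\sigma_g^2 + 2\sigma_e^2)$ |
| ΔCBF, mean baseline | $(\sigma_g^2+\sigma_e^2/2)/(\sigma_g^2+3\sigma_e^2/2)$ |
| ΔCBF, single baseline | $(\sigma_g^2+\sigma_e^2)/(\sigma_g^2+2\sigma_e^2)$ |

The derivation is one observation: error that is *shared* between the two
Δ replicates (a common baseline) migrates into the between-target variance
of the difference score. Subtracting one fixed baseline session shares a
full $\sigma_e^2$; the mean of two baselines shares $\sigma_e^2/2$; paired
subtraction shares nothing. Hence the strict ordering pairs < mean <
single for any $\sigma_e^2 > 0$ — at $\sigma_g^2=\sigma_e^2$ the three
ratios are exactly 1/3, 0.6 and 2/3:

```{r expected}
vc <- variance_components(sigma_b2 = 1, sigma_s2 = 1, sigma_g2 = 1,
                          sigma_w2 = 0)
round(expected_icc(vc), 3)
```

These closed forms are the oracles for every downstream stage: the test
suite verifies them by direct Monte-Carlo simulation of difference scores
at $10^5$ targets, and then checks that the full pipeline (generator →
session means → Δ maps → voxelwise ICC → median) converges to them.

## The voxelwise state contrast

The pain network is defined by a voxelwise two-way ANOVA of the
subject × session table of session means, subjects as blocks, with the
zero-sum contrast $(-\tfrac12, +\tfrac12, -\tfrac12, +\tfrac12)$ over
(S2, S3, S4, S5), i.e. the post-minus-pre mean difference in CBF units:
$t = \sum_s c_s \bar y_{\cdot s} / \sqrt{EMS \sum_s c_s^2 / n}$ on
$(n-1)(s-1)$ error degrees of freedom. The default layout gives
$15 \times 3 = 45$ df, reproducing the printed threshold constants
($t = 2.41$, $z = 2.3$ at one-sided $p < 0.01$). A variance-weighted
mixed-effects fit is not attempted: first-level variance maps do not exist
for simulated data, and the fixed-blocks layout is the one whose error df
matches. Thresholding is voxelwise and one-sided (CBF increases); cluster
correction is out of scope. Blocking makes the t value invariant to
per-subject shifts, and under the null the exceedance rate at the p = 0.01
threshold is calibrated to 1% (checked over $10^4$ simulated voxels).

## Reliability levels

*Inter-subject*: at each voxel a subjects × 2 table (the two same-state
session means, or the two Δ replicates) feeds ICC(3,1); maps are summarised
by the median over a stratum (GM, thresholded network, or an ROI) and by
normalised ICC histograms with sample skewness — reliable measures pile
their mass near 1, giving a pronounced negative skew. Voxels with no
between-subject variance are flagged undefined and excluded from medians
and histograms, with the count logged.

*Within-subject*: ICC$_v$ treats the voxels of an ROI as targets and two
measurements as raters — session means of the two same-state sessions
(inter-session) or pairs of raw scans within one post-surgical session
(intra-session; scans 1 vs 3 and 1 vs 6, spanning start, midpoint and end
of the series). Because the session effect is shared by the scans of a
session it contributes to the *between-voxel* variance within a session,
so intra-session ICC$_v$ exceeds inter-session ICC$_v$ exactly when
$\sigma_s^2$ is appreciable. Voxels are not spatially independent, so the
nominal target count overstates the information content; this is a known
property of the intra-voxel method and no correction is applied. Group
rows are arithmetic means of per-subject ICC$_v$ (the aggregation rule of
the mirrored tables is unstated; the mean is documented, not asserted).

*VAS*: the same machinery applies with subjects as targets. Inter-subject
uses the two post-surgical session means (k = 2; a 16 × 12 all-ratings
layout is selectable via `layout = "all_scans"` since the published layout
is ambiguous), inter-session compares left- vs right-side post session
means, and intra-session uses the six ratings of one side's session
(k = 6). Ratings are session-averaged before k = 2 comparisons, mirroring
the CBF session means. ΔVAS is guarded: when the pre-surgical ratings have
zero variance (the floor effect), a structured refusal record is returned
instead of a coefficient.

```{r guard}
vas <- simulate_vas(study_design(16), seed = 42)
delta_vas_guard(vas, "pain")
```

## Numerical and design choices

- **Undefined vs zero.** Anywhere the ICC denominator is non-positive
  (constant data, zero residual variance) the result is an explicit
  undefined flag, never a silent 0 — zero-filling would distort medians,
  histograms and recovery tests.
- **Residual sums of squares** are clamped at zero against floating-point
  cancellation; the vectorised voxelwise route is tested to 1e-12 against
  the scalar mean-squares route and to machine precision against a
  brute-force sum-of-squares oracle.
- **Histograms** default to 50 equal bins on [-1, 1] (the mirrored figure's
  binning is unstated); fractions are normalised over defined voxels.
- **Atlas handling**: probabilistic ROI volumes are thresholded at an
  inclusive 20% cutoff (percent-scaled inputs auto-detected); overlapping
  thresholded masks are made exclusive by assigning each voxel to the
  higher-probability ROI, ties broken alphabetically, with the overlap
  count reported.
- **Grids** are treated as already co-registered; any shape mismatch is a
  hard error naming both shapes, never a silent resample. The NIfTI affine
  is carried through untouched.
- **Determinism**: every stochastic stage takes a mandatory seed (YAML
  configs without one are refused) and report tables are byte-identical
  under a fixed seed.
- **Default network mask** is a contiguous block of ~10% of GM voxels in
  linear index order — arbitrary and configurable; default ROIs are ten
  small disjoint blocks named after the classic pain-processing regions.

## Problem sizes

The checked claims use: 200 random 8 × 2 tables for oracle equivalence;
2000 tables of 100 targets per true-ICC point for parameter recovery
(±0.02); 200 subjects × 2000 network voxels per replicate run (20 runs in
the tests, 5 in the acceptance script) for the Δ-scheme ordering (±0.03);
$10^4$ voxels for type-I calibration (±0.003); 2000 (tests) or 500
(acceptance script) simulated studies of 16 subjects for the VAS level
ordering; $10^5$ targets for the Monte-Carlo verification of the closed
forms. These sizes make the Monte-Carlo error a fraction of each tolerance
while keeping a full run in minutes on one core.

## Known limitations

The generator is a variance-components emulator, not an ASL physics model:
no spatial smoothness, no motion or labelling artefacts, no
menstrual-cycle or drug effects, Gaussian noise throughout, and VAS
clipping slightly shrinks the nominal variances when parameters push
ratings against the scale bounds. Reproducing the *empirical* ICC values
of the mirrored study is out of scope — the raw scan data are unavailable
— so all quantitative claims are about analytic constants and recovery of
known ground truth, and the qualitative orderings (state > ΔCBF;
single-baseline > mean > paired; intra- > inter-session) that the design
exists to demonstrate.
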