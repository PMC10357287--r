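---
title: "Quantifying iliofemoral tortuosity and calcification for TAVR access risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iliofemoral tortuosity and calcification for TAVR access risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iliorisk)
```

## The problem

Transfemoral TAVR pushes a large-bore sheath (outer diameter 5–7 mm)
through the iliofemoral arteries. When the vessel is narrow, calcified or
tortuous, the sheath can dissect, perforate or otherwise injure it. The
minimal lumen diameter (MLD) alone is a poor guide in tortuous anatomy, so
this package scores the *combination* of tortuosity and lumen calibre:

* `SOA` — the sum of all curve angles along the analyzed segment
  (deviation-from-straight convention: 0° is straight, a right-angle elbow
  is 90°);
* `NOC` — the number of curves;
* `CSI = SOA × NOC / MLD` — high risk above 100;
* `SFAR = sheath OD / MLD` — high risk above 1.00;
* `IFT = (true/ideal length − 1) × 100` — the classic length-ratio
  tortuosity index, reported for comparison;
* calcification categories I–IV from the fractions of wall perimeter and
  lumen a plaque occupies (≥ III is the high-risk grade).

The classifier is a two-step threshold tree — SFAR > 1.00 first, CSI > 100
second, both strict — because the two steps capture distinct mechanisms
(sheath–vessel mismatch versus tortuosity) and their order fixes the
attribution reported as `triggering_step`. The (SFAR, CSI) quadrants QI–QIV
summarize which mechanism dominates in a cohort.

## Measuring a centerline

Input centerlines are ordered 3D polylines (mm) with a lumen cross-section
per point, running puncture site → aortoiliac bifurcation. Measurement
proceeds in four deterministic stages:

1. **Resample** to uniform 1 mm arc-length spacing (linear interpolation).
2. **Smooth** coordinates with a 5 mm moving average whose window shrinks
   at the ends so both endpoints are preserved. Cross-sections are
   interpolated, never smoothed, so lumen minima are untouched.
3. **Profile**: at every grid point, the deviation angle between probe
   chords drawn 10 mm backwards and forwards along the vessel.
4. **Segment**: curves are maximal runs of the profile above a 5° noise
   floor; local maxima closer than 20 mm merge (keeping the larger peak,
   which prevents double-counting one anatomic bend); curves whose angle is
   below 15° are discarded.

A curve's reported angle is the **total tangent rotation across its span**,
not the profile peak. The probe-chord angle at the peak of a gradual bend
underestimates the true turn by roughly `θ·Rθ_rad/(4·offset)` (a 50° bend
of 15 mm radius reads ≈ 33°), because each 10 mm chord averages over part
of the bend. The tangent rotation equals the geometric bend angle for a
planar bend of *any* radius, which is what makes the planted-geometry
recovery tests exact to within discretization error (< 2° over hundreds of
simulated vessels). The profile is still what localizes curves, assigns
their spans and sets the noise floor.

Defaults (spacing 1 mm, window 5 mm, offset 10 mm, floor 5°, merge 20 mm,
minimum angle 15°) reproduce the expected ~3 curves on normal iliofemoral
anatomy and are all explicit arguments of `detect_curves()`.

Two numerical notes. First, a moving average is not a projection, so
re-applying `resample_smooth()` moves points on curved segments by
`≈ κ·w²/24` per pass (about 0.07 mm at a 15 mm bend radius); the pipeline
therefore smooths exactly once, and the test suite asserts repeat
application stays within 0.15 mm and that the downstream angles are stable
to 0.5°. Second, `tortuosity_profile()` takes its true/ideal lengths from
the centerline *as supplied* (not from the smoothed working copy), which
keeps IFT exactly invariant to rigid motion and uniform scaling.

## Plaques and the free lumen

A calcified plaque is modeled as a circular segment of sagitta `t` (its
radial thickness) on one wall. Realigning the centerline to the free lumen
shifts each in-span point radially away from the plaque wall by the exact
centroid displacement of a disc minus that segment,

\[ s(t, r) = \frac{2}{3} r \frac{\sin^3\alpha}{\pi - \alpha + \sin\alpha\cos\alpha},
   \qquad \alpha = \arccos(1 - t/r), \]

which behaves like \(t^{3/2}/\sqrt{r}\) for small plaques: strictly
increasing in thickness and *larger in smaller vessels* — the reason the
same plaque perturbs a 5 mm vessel's angle more than a 10 mm vessel's. The
shift tapers linearly over 5 mm at the span edges (an artifact constant,
argument `taper`), circumferential plaques produce no net shift, and
in-span diameters are reduced by the plaque thickness.

Wall positions follow the tip/bottom taxonomy of a bend: `inner_wall` is
the apex (convex) side, so its plaque pushes the lumen line toward the
bend's center and *straightens* the measured angle (`delta < 0`);
`outer_wall` is the concave side and *sharpens* it (`delta > 0`);
`circumferential` leaves it unchanged. For plaques up to 30% of the lumen
radius the angle change stays within about 10% of the curve's angle — an
emergent property of the geometry above, asserted in tests, not a clamp.
`poc_angle_effect()` measures the original and realigned angles with the
same interpolating probe so that a zero shift yields delta exactly 0.

## Cohort statistics

Everything needed to derive and validate such a model on a cohort table:

* **Confusion metrics** as exact fractions, with zero-denominator metrics
  reported as undefined (`NA`), never 0, plus the conventional one-decimal
  percentages.
* **ROC / C-statistic** via pairwise concordance (ties count ½) with
  DeLong 95% intervals (`pROC` underneath; a brute-force concordance count
  is the independent oracle in the tests).
* **Maximum-accuracy threshold**: exhaustive scan over midpoints of
  adjacent distinct scores plus ±∞, ties broken toward higher sensitivity,
  then the lower threshold.
* **Logistic regression** by IRLS (`stats::glm`), with exactly collinear
  columns and (quasi-)separation raised as errors naming the culprit
  feature; for Bernoulli outcomes the AIC equals deviance + 2·parameters.
* **Minimum-AIC forward selection** from univariate-screened candidates
  (p < 0.05; Welch t / Mann–Whitney for continuous, chi-square / Fisher for
  categorical). Greedy forward addition is the simplest procedure
  consistent with "minimum AIC" selection; AIC ties break alphabetically,
  making the whole path deterministic.
* **Propensity matching**: logistic propensity scores, cases processed in
  descending score order, each taking its nearest 2 unused controls within
  a 0.10 caliper on the probability scale (the `logit_sd` convention is
  available), unmatched cases dropped and reported, balance summarized as
  standardized mean differences. Greedy descending-order nearest neighbor
  is the common convention where none is stated.
* **Threshold discovery**: depth-2 recursive partitioning with exhaustive
  Gini split search over midpoints. Cascade-shaped trees convert exactly to
  the ordered two-rule model; on noisy data where both children split, the
  first threshold per feature is taken (risk is monotone in both features
  here), flagged as a summary rather than an exact rewrite.
  `derive_ivc_model()` orders SFAR before CSI — with strict ">" rules the
  prediction is order-free; only the step attribution changes.
* **Calibration slope** of outcome on logit(probability), with a seeded
  bootstrap bias correction (`2·apparent − mean(bootstrap slopes)`,
  200 resamples by default).

## The simulator

`simulate_vessel()` builds straight segments joined by planar circular-arc
elbows (radius 15 mm), each elbow's plane rotated uniformly at random about
the running axis for 3D realism. Stated study conditions are defaults:
stretched length N(205, 13) mm; curves 2 + Poisson(1.4) for normal versus
2 + Poisson(3.6) for complication-prone anatomy; MLD truncated-normal
6.8 (SD 1.0) versus 5.6 (SD 0.8) mm with a 3 mm floor; high-grade
calcification in 21.8% versus 33.7%; overall incidence 7.2%; complication
types in the 36/25/19.8/16.3/2.9% mix. Free choices, made once on domain
grounds: per-curve angles Gamma (shape 18) truncated to [20°, 85°] around
the group mean angle (≈ SOA/NOC of each group; bends under ~15–20° are not
what a reader would call a curve); sheath OD truncated-normal 5.85 (SD 0.5)
mm, anchored so the control-group SFAR centres near 0.86; baseline lumen
1.0–2.5 mm above the MLD with one Gaussian stenotic dip planted exactly at
a grid point (so MLD recovery is exact); plaque spans 10–25 mm with
thickness 0.3–1.0 mm capped at 28% of the local radius; 15% of patients in
the high-risk anatomy stratum; coordinate noise 0 by default, since
software-extracted centerlines are already smooth spline fits (a `noise_sd`
field exists for robustness experiments).

Outcomes follow a logistic mechanism on the *extracted* features
(SOA, NOC, MLD, SFAR > 1, CAG ≥ III) — extracted by running the actual
measurement pipeline, not copied from the planted values — with
direction-correct coefficients that are package configuration, not
estimates. The intercept (−2.4849) was calibrated by root-finding on 10⁵
latent draws so the default cohort hits 7.2% incidence
(`calibrate_intercept()` reproduces it). Every patient is generated from a
deterministic substream of the master seed, so any row is regenerable
bit-exactly from (config, seed, index).

What the simulator does **not** emulate: imaging noise and partial-volume
effects, non-circular lumens, plaque composition, vessel wall compliance,
or any correlation structure between demographics and anatomy beyond the
mild imbalances used to exercise the matching step. Passing tests therefore
demonstrate the *software* measures geometry correctly and the statistics
behave as specified — not that the score's clinical operating
characteristics transfer to real CT data.

## Problem sizes and tolerances

The test suite uses the sizes at which each property is informative:
200 seeded vessels for planted-geometry recovery (NOC exact, angles within
2°); a 20,000-patient cohort for coefficient recovery (signs plus 3
standard errors) whose first 10,000 rows check incidence calibration
(7.2% ± 1 absolute); 500 random tables (n ≤ 50) for AUC–concordance
equality to 1e-12; 2,000-point planted-rule samples for threshold recovery
within half the planted margin. Statistical assertions use tolerances of
about 4 standard errors of the quantity under test so they are sharp but
not seed-lottery tests. The planted-rule fixture alternates SFAR around 1
in CSI order so that no same-label pocket abuts the threshold gap —
otherwise the empirical Gini optimum legitimately moves off the planted
boundary (rpart picks the identical off-gap cut, which the suite verifies
on a one-feature-dominant sample).

## Known limitations

* Curve segmentation parameters are calibrated for iliofemoral scale
  (~200 mm, bends ≥ 15°); coronary-scale vessels would need different
  defaults.
* The cascade-to-rules conversion assumes risk increases in every tree
  feature; a feature with protective direction would need `"<="` rules,
  which the rule engine supports but the converter does not emit.
* The plaque model treats lesions as rigid circular segments; real plaque
  compliance and non-circular lumens are out of scope.
* DeLong intervals assume independent observations; clustered or matched
  designs would need a resampling interval.
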