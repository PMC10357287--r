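# iliorisk

Quantitative risk assessment of **iliofemoral vascular complications (IVC)**
for transfemoral transcatheter aortic valve replacement (TF-TAVR).

Large-bore TAVR sheaths are advanced from the femoral puncture site through
the iliofemoral arteries. In calcified, narrow and tortuous vessels this
remains one of the most common sources of procedural complications
(dissection, perforation, pseudoaneurysm, thrombosis/embolism, AV fistula),
yet tortuosity is still mostly judged by eye. `iliorisk` is for
interventional imaging analysts and biostatisticians who want that judgment
quantified: it measures vessel tortuosity and calcification from a 3D
centerline (as exported from CT analysis software) and turns the
measurements into an explicit, auditable risk classification — and it ships
a synthetic vessel/cohort simulator so the entire pipeline can be developed
and validated without patient data.

## The score and the model

For a centerline running from the puncture site to the aortoiliac
bifurcation, with detected curves `1..NOC` of deviation angles `θ_i`
(degrees, 0° = straight), minimal lumen diameter `MLD` (mm) and sheath outer
diameter `OD` (mm):

```
SOA  = Σ θ_i                      sum of all curve angles
CSI  = SOA · NOC / MLD            Cedars-Sinai Index
SFAR = OD / MLD                   sheath-to-femoral-artery ratio
IFT  = (true length / ideal length − 1) × 100
```

The classification is a two-step threshold tree, evaluated in order:

1. **SFAR > 1.00** → high risk (sheath wider than the narrowest lumen);
2. otherwise **CSI > 100** → high risk (tortuosity–lumen mismatch);
3. otherwise low risk.

Both thresholds are strict; boundary values fall through. The (SFAR, CSI)
plane is reported as quadrants QI–QIV (QI = both below threshold, the
event-free region; QIV = SFAR ≤ 1 but CSI > 100, the most common anatomy
among complications). Calcified plaques are graded I–IV from the fraction
of the wall perimeter and of the lumen they occupy (≥ III is the high-risk
grade), and a plaque sitting on a curve shifts the free-lumen centerline,
which perturbs the measured angle by up to about 10%.

Beyond per-patient scoring, the package implements the full derivation and
validation machinery for this class of models: univariate screening,
minimum-AIC forward logistic selection, 2:1 nearest-neighbor propensity
matching with a 0.10 caliper, Gini recursive partitioning for threshold
discovery, ROC/C-statistics with DeLong intervals, exact-rational confusion
metrics, and an optimism-corrected calibration slope.

## Worked example

Simulate one complication-prone vessel and assess it against the published
two-step model:

```r
library(iliorisk)

v <- simulate_vessel(sim_config(), stratum = "highrisk", seed = 33)
a <- assess_patient(v$centerline, v$plaques, sheath_od = 5.5)
a
#> IVC risk assessment
#>   CSI 132.1 | SFAR 1.07 | quadrant QIII
#>   calcification category: none
#>   prediction: high_risk (sfar_step)
a$profile
#> Tortuosity profile
#>   curves (NOC):        5
#>   sum of angles (SOA): 135.4 deg
#>   max angle:           36.0 deg
#>   mean curve spacing:  39.0 mm
#>   true / ideal length: 207.2 / 195.2 mm (IFT 6.1%)
a$lumen
#> Lumen: MLD 5.12 mm (at 59 mm), min area 20.6 mm^2, min perimeter 16.1 mm, mean diameter 6.51 mm
```

Reading: the vessel has 5 curves summing to 135°, and its narrowest lumen
(5.12 mm, located 59 mm from the puncture site) is narrower than the
5.5 mm sheath, so SFAR = 5.5/5.12 = 1.07 exceeds 1.00 and the first step
already flags the patient; CSI = 135.4 × 5 / 5.12 = 132 would have flagged
them at the second step anyway (quadrant QIII: both mechanisms present).

The same pipeline runs from the shell via the bundled CLI
(`inst/cli/iliorisk`): `score`, `evaluate`, `derive` and `simulate` verbs
over the CSV/JSON formats documented in `?read_centerline`,
`?read_plaques` and `?read_cohort`.

Deriving a model from a cohort table and evaluating it:

```r
cohort <- simulate_cohort(sim_config(), n = 2000, seed = 1)
model  <- derive_ivc_model(cohort)   # matching -> screening -> AIC -> tree
model
#> Iliofemoral vascular complication risk model
#>   step 1: high risk if sfar > ...
#>   step 2: high risk if csi > ...
#>   otherwise: low risk
evaluate_model(ivc_default_model(), cohort)
```

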