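# drgsqa

Routine linac QA for volumetric-modulated arc therapy (VMAT) probes whether a
machine holds its output steady while it simultaneously modulates dose rate,
gantry speed, and MLC positions. The standard dose-rate/gantry-speed (DRGS)
strip test delivers a uniform dose to seven MLC-defined strips, each with a
different dose-rate/gantry-speed combination — but the stock test plan only
reaches modest monitor-units-per-degree (MU/deg) values, well below what
stereotactic body radiotherapy (SBRT) arcs demand. `drgsqa` is a toolkit for
medical physicists that closes that gap:

- **profile** the MU/deg kinematics of arc DICOM RT Plans control point by
  control point, and compare a clinic's plan population against what its QA
  plan actually tests;
- **rescale** a DRGS test plan's total MU so its maximum MU/deg surpasses the
  clinical maximum, forcing the gantry to the slow speeds SBRT deliveries
  reach, while checking the machine's deliverability ceiling;
- **analyze** the paired EPID strip/open-field portal images a DRGS delivery
  produces, computing a per-ROI percent deviation statistic and flagging it
  against stored machine baselines.

## The statistics

An RT Plan samples the machine state at control points (CPs). For the segment
between consecutive CPs,

```
MU/deg = (MU/CP) / (deg/CP)
```

where MU/CP is the meterset delivered across the segment (beam MU × the
cumulative-weight increment, normalized by the final cumulative weight) and
deg/CP is the gantry arc length, unwrapped across the 0/360 boundary along
the beam's rotation direction. MU/deg is a proxy for gantry speed: above the
machine's *critical* value

```
(MU/deg)_critical = (MU/min)_max / (60 × (deg/s)_max)
```

the dose rate is saturated and the machine must slow the gantry. For a
TrueBeam flattened beam (600 MU/min, 6 deg/s) the critical value is
**1.67 MU/deg**.

For the image analysis, the strip image is divided pixelwise by the
open-field image to cancel the beam profile, and each strip ROI's deviation
is its mean corrected reading relative to the mean over all strips:

```
deviation_i (%) = 100 × (mean_i / mean(all segments) − 1)
```

New measurements are differenced against per-ROI baselines as
`100 × (measured/baseline − 1)` with a default ±3% tolerance.

## Worked example

```r
library(drgsqa)

limits <- machine_limits(max_dose_rate = 600, max_gantry_speed = 6,
                         max_mu_per_deg = 60)
critical_mu_per_deg(limits)
#> [1] 1.666667   # prints as 1.67 MU/deg

plan <- make_vendor_replica_plan()   # synthetic 7-strip DRGS plan, 250 MU
mu_per_deg(plan$beams[[1]])
#>    beam_id segment_index mu_per_cp deg_per_cp mu_per_deg undefined
#> 1 DRGS arc             1      10.0         25      0.400     FALSE
#> ...
#> 7 DRGS arc             7      56.8         25      2.272     FALSE

scale_plan_mu(plan, 10, limits = limits)$result
#> <scaling_result> x10: 250 -> 2500 MU, max 2.27 -> 22.72 MU/deg  [deliverable]
```

The stock plan tops out at 2.272 MU/deg — barely above the critical value —
while a 10× MU rescale reaches 22.72 MU/deg without touching the geometry,
still below the 60 MU/deg deliverability ceiling.

Image analysis on a synthetic pair with a planted +3% perturbation on ROI 4
(0.5% noise):

```r
set.seed(1)
pair <- make_epid_pair(factors = c(1, 1, 1, 1.03, 1, 1, 1), noise_sd = 5)
dev <- segment_deviations(corrected_image(pair$strip, pair$open),
                          locate_rois(pair$layout, pair$strip))
compare_to_baseline(dev, baseline_record("TB1", rep(1, 7)), tolerance_pct = 3)
#> <qa_report> tolerance 3%
#>   ROI 1  measured 0.9999  baseline 1  difference -0.0%  PASS
#>   ...
#>   ROI 4  measured 1.03    baseline 1  difference +3.0%  FAIL
#>   max |difference| 3.0%  => FAIL
```

The deviation of the perturbed ROI is 2.56% (the grand mean absorbs part of
the perturbation: (1.03/(1 + 0.03/7) − 1)×100 = 2.5605), while the baseline
difference sees the full 3.0% shift and flags it.

## Command line

A thin wrapper over the same functions lives at `exec/drgsqa`:

```sh
drgsqa profile --plans a.dcm,b.dcm --max-dose-rate 600 --max-gantry-speed 6 --out report/
drgsqa scale   --plan T2_DRGS.dcm --out T2_DRGS_x10.dcm --factor 10
drgsqa analyze --strip strip.dcm --open open.dcm --layout layout.json \
               --baseline baseline.json --tolerance 3
drgsqa fixtures --kind vendor --seed 1 --out fixtures/
```

Exit codes: 0 pass, 1 I/O or usage error, 2 QA failure (tolerance or
deliverability).

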