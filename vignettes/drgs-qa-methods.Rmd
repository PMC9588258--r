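---
title: "Dose-rate/gantry-speed QA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-rate/gantry-speed QA: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgsqa)
```

## The problem

A VMAT delivery modulates dose rate, gantry speed, and MLC aperture at the
same time. The machine's control system trades the first two off against
each other: as long as the requested monitor units per degree of rotation
(MU/deg) stay below a critical value, the gantry can run at full speed and
the dose rate does the modulating. Beyond it, the dose rate is pinned at its
maximum and the gantry must slow down. That critical value is

$$\left(\mathrm{MU/deg}\right)_{crit} =
  \frac{(\mathrm{MU/min})_{max}}{60 \times (\mathrm{deg/s})_{max}},$$

1.67 MU/deg for a flattened-beam TrueBeam (600 MU/min, 6 deg/s); a
flattening-filter-free machine with a higher nominal dose rate has a
proportionally higher critical value and can be described here simply by a
different `machine_limits()` configuration.

Routine QA uses a dose-rate/gantry-speed (DRGS) strip test: an arc beam
delivers a nominally uniform dose to seven MLC-defined strips, each strip
pairing a different dose rate with a different gantry speed, followed by an
open field. If the test plan's MU/deg range sits mostly *below* the critical
value, it never exercises the slow-gantry regime that stereotactic (SBRT)
arcs live in. The toolkit therefore (a) measures the MU/deg distribution of
clinical plans, (b) rescales the test plan's MU so its maximum MU/deg
surpasses the clinical maximum, and (c) analyzes the resulting strip/open
EPID image pair against machine baselines.

## Plan kinematics

An RT Plan beam is a control-point (CP) sequence; each CP carries a gantry
angle, a cumulative meterset weight, and MLC positions. For segment $i$
(between CP $i$ and CP $i+1$):

- $\mathrm{MU/CP}_i = \mathrm{MU}_{beam}\,(w_{i+1}-w_i)/w_{final}$. The
  final cumulative weight is read from the file, not assumed to be 1 —
  legal files normalize to arbitrary totals.
- $\mathrm{deg/CP}_i$ is the arc length along the beam's stated rotation
  direction, computed as a directional difference modulo 360 so that
  crossing the 0/360 boundary (e.g. 350° → 10° clockwise = 20°) is handled
  in one branch. Angles of exactly 360 are normalized to 0 on read, keeping
  every angle in the IEC 61217 interval $[0, 360)$.
- $\mathrm{MU/deg}_i = \mathrm{MU/CP}_i / \mathrm{deg/CP}_i$.

**Zero-arc segments.** A segment where the gantry holds still while MU are
delivered has $\mathrm{deg/CP} = 0$; its MU/deg is physically undefined,
not an error. Such segments carry `NA`, are flagged `undefined`, are
excluded from histograms and exceedance fractions, and are tallied
separately so the pooled counts stay honest. Static beams (rotation `NONE`,
such as the DRGS open field) are modeled and written, but contribute no
kinematic segments.

**Counting convention.** MU/deg needs a CP *pair*, so the natural unit is
the inter-CP segment ($n_{CP}-1$ per beam). Summaries report both the
segment count and the CP count, since "control points analyzed" is commonly
used loosely for either.

## Plan scaling

`scale_plan_mu()` multiplies every beam meterset — strips *and* open field —
by one uniform factor and touches nothing else. Because weights and angles
are untouched, every defined segment's MU/deg scales by exactly the factor,
and the strip/open normalization of the image analysis is preserved.
`required_scale_factor()` finds the smallest factor (smallest integer by
default) whose scaled maximum *strictly exceeds* the target; strictness
matters because the point of the modified plan is to test beyond everything
the clinic delivers, not at it. Deliverability is a flag, not an exception:
a scaled plan whose maximum MU/deg exceeds the machine ceiling
(`max_mu_per_deg`, 60 MU/deg for a TrueBeam) is still a valid object to
inspect.

## Image analysis

The strip image is divided pixelwise by the open-field image; the ratio
cancels beam-profile structure, panel gain, and any common intensity scale
(the analysis is invariant to multiplying both images by a constant).
Pixels where the open-field reading falls below a floor — default 5% of the
open image's median — are masked and excluded from every average; inside
the field this mask never triggers, but it makes the operation total on
arbitrary input.

Each strip's ROI is its aperture eroded on every side by
`margin_fraction` × strip width (default 0.25), keeping the sample inside
the flat strip core and away from penumbra; the penumbra width is machine-
and energy-dependent and a quarter-width erosion is a conservative choice.
ROIs are ordered left to right. The deviation of segment $i$ is

$$D_i = 100\left(\frac{\bar{c}_i}{\frac{1}{n}\sum_j \bar{c}_j} - 1\right),$$

with the grand mean taken as the *unweighted mean of segment means* rather
than the pooled-pixel mean. This choice makes $\sum_i D_i = 0$ exactly even
when ROIs have unequal pixel counts, which in turn gives the test suite a
sharp invariant; with the pipeline's disjoint equal-width ROIs the two
definitions differ negligibly.

Baseline comparison is the same ratio form, per ROI:
$100(\text{measured}/\text{baseline} - 1)$, flagged against a default 3%
tolerance (the conventional per-ROI limit for this test). At the 1-decimal
precision reports are printed with, the ratio form and the
difference-in-percentage-points form are numerically indistinguishable for
readings near 1; the ratio form was chosen for consistency with the
deviation statistic. Baselines are arithmetic per-ROI means over historical
sessions, stored as JSON with provenance (machine, date range, session
count).

## Synthetic fixtures: what they emulate, and what they don't

No vendor test file or clinical plan can be redistributed, so every fixture
is generated:

- **Vendor-replica DRGS plan.** Seven strip segments of 25° each
  (arc 181°→356° CW), MU/deg schedule
  `0.4, 0.6, 0.8, 1.0, 1.2, 1.728, 2.272` (10–56.8 MU per strip, 200 MU
  arc) plus a 50 MU static open field: 250 MU total, maximum segment
  exactly 2.272 MU/deg, so a 10× rescale reaches 22.72 MU/deg. The real
  test file's internal CP table is not public; this layout reproduces its
  published constraints (7 strips, 250 MU, the ×10 = 22.72 relationship),
  which is exactly what the toolkit's arithmetic depends on. It does not
  claim to match the confidential file segment-for-segment.
- **SBRT-like cohort.** Defaults emulate a 21-plan stereotactic cohort:
  3822 pooled segments (182 per plan, 1.9° each), per-segment MU/deg drawn
  from a clipped log-normal below the vendor-replica maximum, with a
  planted pooled maximum of 21.29 MU/deg and a planted 83% of segments
  above 2.272 MU/deg. The planted features make distribution summaries
  exactly verifiable; the log-normal body is a realism choice for
  right-skewed modulation distributions, not a fitted model.
- **EPID pairs.** The open image is a smooth radially symmetric profile
  (peak 1000 detector units, 15% corner fall-off on a 1024×768,
  0.336 mm/px panel — representative megavolt-imager geometry); the strip
  image is the open image masked to seven vertical 20 mm strips at 30 mm
  pitch (the same millimeter geometry the replica plan's MLC encodes, so
  plan-derived and generator layouts agree), multiplied by per-ROI
  perturbation factors, plus seeded additive Gaussian noise.

What the fixtures deliberately omit: scatter, panel lag/ghosting and sag,
flood-field residuals, penumbra shape, MLC transmission, and the site mix
of a real SBRT population. Passing tests therefore demonstrate the
*analysis* is correct — planted perturbations are recovered through the
closed form $100((1+\delta)/(1+\delta/n)-1)$ to four significant figures at
zero noise — not that a physical panel behaves ideally.

## DICOM handling

The package includes a purpose-built DICOM codec for the RT Plan / RT Image
element subset the toolkit reads and writes (explicit and implicit VR
little endian on read; explicit VR on write; nested sequences in both
defined- and undefined-length form). Decimal strings are formatted to fit
DICOM's 16-byte limit; values round-trip to better than 1 part in 10^9.
Two writers serve two contracts: `write_plan_dicom()` serializes a plan
from scratch (fixtures), while `write_rtplan()` re-serializes a template
changing only the referenced beam metersets and the instance UID, so
modifying a vendor file preserves every unmodeled element byte-for-byte.
Attributes that files state only on change (gantry angle, rotation
direction, MLC positions) are carried forward across CPs on read. The
reader is tolerant of unrelated elements; only modeled fields are
validated, and validation (`validate_plan()`) returns findings rather than
exceptions so a QA workflow can report all problems at once.

## Numerical choices and degenerate inputs

- Monotonicity of cumulative weights is enforced with a 1e−12 slack on
  read (binary-to-decimal string round trips), and exactly in
  `validate_plan()`.
- The last CP's weight must reach the final cumulative weight within 1e−6
  relative.
- Integer `required_scale_factor()` guards its `floor`+1 candidate against
  floating-point edge cases by direct verification of the strict
  inequality; the real-valued variant returns the target ratio nudged up
  by 1e−9 relative.
- Display rounding (MU/deg to 2 decimals, percent differences to 1
  decimal) happens only in print methods and reports; all stored values
  keep full precision.
- Fixture determinism: generators take a `seed`; UIDs are drawn from R's
  RNG so a fixed seed reproduces output files byte-identically.

## Problem sizes in the test suite

Pixel-level tests run on geometrically scaled-down panels (e.g. 256×96 px
at 1.344 mm/px — the same field of view as the full-size default) because
every statistic here is a mean over an ROI: results are independent of
resolution up to quantization, which dedicated tests cover at full default
size. Property tests use 200–1000 randomized small beams for the angle
unwrapping oracle and 100 random image fixtures for the zero-mean
invariant.

## Known limitations

- No reconstruction of instantaneous dose rate or gantry speed versus time
  (that requires delivery log files, not plans), and no MLC-speed test
  analysis.
- No automatic strip detection from image content: ROI localization is
  layout- or plan-driven.
- No absolute dosimetry, gamma analysis, or panel characterization; images
  are assumed already flood-field corrected by the acquisition system.
- The DICOM codec covers the QA subset, not the full standard (no
  encapsulated/compressed transfer syntaxes, no big-endian).
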