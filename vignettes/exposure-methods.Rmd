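---
title: "Methods: screening-level plasticizer exposure from children's products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening-level plasticizer exposure from children's products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastexpo)
```

## Scope and model

`plastexpo` implements a screening-level consumer-exposure assessment for
six plasticizers — five phthalate esters (DBP, DEHP, DEP, DIBP, DINP) and
one adipate alternative (DEHA) — measured in surveys of children's
products grouped into six categories (accessories, mats, shoes,
stationery, toilet products, toys). Two exposure routes are modelled,
following the algorithm structure of the U.S. EPA Consumer Exposure Model
(CEM): ingestion of chemical migrating into saliva during mouthing, and
dermal absorption from direct contact. Inhalation and indoor-dust
ingestion are out of scope — their indoor concentrations are driven by
sources other than an individual product, and the screening question here
is attribution to the surveyed products themselves.

### Ingestion

$$\mathrm{dose_{ing}} = \frac{MR \cdot CA \cdot D_{mouthing} \cdot ED}{BW \cdot AT}$$

with $MR$ the migration rate from article to saliva (mg cm^-2^ h^-1^),
$CA$ the mouthed contact area (cm^2^), $D_{mouthing}$ the mouthing
duration (min per hour of product use), $ED/AT$ the exposure-duration to
averaging-time ratio and $BW$ body weight (kg). Because the printed form
mixes time bases (a per-hour flux, mouthing minutes per hour, a per-day
dose), the implementation makes the accumulation explicit:

```
dose = MR * CA * (D_mouthing / 60) * use_hours * ED / (BW * AT)
```

where `use_hours` is the daily duration of product use (h/d). $MR$ is not
measured; the screening convention assigns it from the chemical's content
class. The default two-level policy maps content at or above 1% w/w to
10 mg cm^-2^ h^-1^ and below 1% to 0.1; the four-level CEM ladder
(10, 0.1, 10^-3^, 10^-4^) is available for the sensitivity analysis.
Boundaries are inclusive upwards (exactly 1% receives the high rate).

### Dermal absorption

$$\mathrm{dose_{derm}} = C_{art} \cdot \frac{SA}{BW} \cdot l \cdot FA \cdot \frac{ED}{AT}$$

$C_{art}$ is the article-phase concentration (mg cm^-3^ = mass fraction
× article density), $SA/BW$ the exposed (hands-only) skin area per body
weight, $l$ the distance the chemical diffuses within the article during
one contact, and $FA$ the fraction of the skin load absorbed rather than
evaporated. The micro-model:

* **Diffusion distance** $l = 2\sqrt{D \cdot Dur/60}$ (m, converted to
  cm), with $D$ the solid-phase diffusivity (m^2^/h) and $Dur$ the
  contact duration (min). The literal linear product $2 \cdot D \cdot
  Dur/60$ is dimensionally inconsistent for a length; the square-root
  diffusion-length reading restores units and is the default, with the
  literal form retained behind `literal = TRUE` for auditing.
* **Lag time** $t_{lag} = h_{sc} / (6 \cdot 10^{-2.8 - 0.0056\,MW})$ (h),
  with stratum corneum thickness $h_{sc}$ = 15 μm by default.
* **Permeability** $K_p = \left[ (K_{lip} + K_{pol})^{-1} + K_{aq}^{-1}
  \right]^{-1}$: lipid and polar-pore pathways in parallel, in series with
  the aqueous boundary layer. The component correlations are not part of
  the screening publication lineage this package reproduces, so documented
  standard forms are used — Potts–Guy for $K_{lip}$, an aqueous-pore term
  $1.5\times10^{-4}/\sqrt{MW}$ for $K_{pol}$, and the Cleek–Bunge boundary
  layer $2.6/\sqrt{MW}$ for $K_{aq}$ — and each can be pinned per chemical
  in the registry file, which isolates this modelling gap.
* **Volatility ratio** $\chi = h \cdot p_{vap} \cdot MW / (K_p \cdot S_w
  \cdot R \cdot T)$ with $R$ = 62.37 mL Torr K^-1^ mmol^-1^; the
  gas-phase coefficient $h$ (m/h) is converted to cm/h before dividing so
  the ratio is dimensionless.
* **Fraction absorbed**
  $FA = \dfrac{3 + \chi\,[1 - e^{-a\,Dur_h/t_{lag}}]}{3\,(1 + \chi)}$,
  with the contact duration in hours so the exponent is dimensionless.
  The grouping is fixed so that a non-volatile chemical ($\chi = 0$) is
  fully absorbed and a highly volatile one under long contact approaches
  1/3 — the parse under which sparingly water-soluble chemicals (large
  $\chi$ through small $S_w \cdot K_p$) show depressed dermal uptake,
  which is the qualitative behaviour the screening literature reports for
  DEHA, DEHP and DINP.

### Margin of exposure

$\mathrm{MOE} = \mathrm{RfD}/\mathrm{dose}$ per chemical, against
NOAEL/LOAEL-derived reference doses (2, 3, 750, 125, 15 and 170
mg kg^-1^ d^-1^ for DBP, DEHP, DEP, DIBP, DINP, DEHA; basis strings are
carried in the registry). MOE below 100 is flagged as the screening
concern level; a dose of zero yields an undefined (NA) margin, never an
infinity.

## Calibration of the default factor set

The CEM defaults used in the original screening are not all public; the
screening *outputs* are. Two of them pin the two least-constrained
factors, and `default_exposure_factors()` solves both in closed form:

* `use_hours` is set so that the high-migration scenario
  (MR = 10 mg cm^-2^ h^-1^) yields exactly 5.0 × 10^-1^ mg kg^-1^ d^-1^.
  With the conventional child defaults (CA = 10 cm^2^, mouthing 6 min/h,
  BW = 15 kg, ED = AT), this gives 0.75 h/d of mouthing-relevant use.
* the solid-phase diffusivity `D` is set so that DEHP at the 100 mg/kg
  inclusion-threshold concentration yields a dermal dose of exactly
  8.6 × 10^-6^ mg kg^-1^ d^-1^. Since $FA$ does not depend on $D$, the
  required $l$ — and hence $D \approx 1.7\times10^{-16}$ m^2^/h, within
  the range reported for plasticizer diffusion in rigid PVC — follows
  directly.

Because both dose equations are strictly linear in their scaling input
(MR, $C_{art}$), these two anchors propagate: the low-migration scenario
is exactly 100× lower (5.0 × 10^-3^), and the dermal maxima scale as the
concentration ratio (for DEHP: 1.7 × 10^-2^ at 20.13% w/w in mats,
2.9 × 10^-2^ at 33.68% w/w in stationery). Every factor remains
individually overridable; the calibration functions
(`calibrate_use_hours()`, `calibrate_diffusivity()`) are exported so the
anchoring is reproducible and inspectable.

Other defaults, each a deliberate choice where the source chain is
silent: article density 1.2 g cm^-3^ (typical plasticized PVC) for the
mass-fraction-to-volume conversion; the absorption rate constant `a` = 1
(dimensionless); contact duration 60 min; T = 298 K; gas-phase
mass-transfer coefficient 10 m/h.

## Survey handling

Concentrations are stored in mg/kg; percent w/w is accepted on input and
converted (1% = 10,000 mg/kg). Non-detects carry a missing concentration
until `substitute_nondetects()` imputes LOQ/2 explicitly (LOQs: 30.6,
32.5, 44.0, 33.1, 35.6, 41.0 mg/kg for DBP, DEHP, DEP, DIBP, DINP,
DEHA). Deterministic screening uses detected values only, after
`filter_for_exposure()` retains detections strictly above 100 mg/kg; the
probabilistic concentration fits use detected plus substituted values.
The strict reading of the threshold means a cell whose maximum sits
exactly at 100 mg/kg (two cells in the default synthetic survey) is
screened out of the deterministic table.

The deterministic minimum-exposure scenario evaluates the inclusion
threshold concentration (0.01% w/w) rather than the observed cell
minimum: this is the unique convention under which the per-chemical
minimum dermal dose is constant across categories, which is the pattern
the published screening table shows (e.g. one DEHP dermal minimum
repeated in five categories).

## Monte Carlo engine

Per iteration and age group (0–2 and 3–12 years), the engine draws body
weight, hand surface area, mouthing contact area and duration,
diffusivity, a daily activity duration per category (accessories = stay
in home, shoes = stay out of home, mat and toy = playing, stationery =
study, toilet = personal sanitation), and a concentration per
(chemical, category) cell from its fitted lognormal; it evaluates both
dose equations per category, sums across the six categories within the
iteration, and reports the median and 95th percentile per route over
10,000 iterations (the default). Choices that matter:

* **Censoring**: cell distributions are fitted to detected values plus
  LOQ/2 substitutes by matching the mean and SD of the logs; a degenerate
  cell (all non-detects) becomes a point mass, and a cell with fewer than
  two measurements is skipped with an explicit marker.
* **Induced migration rate**: MR is not sampled directly; each sampled
  concentration is mapped through the migration-rate policy, so MR's
  distribution is the induced two-point (or four-point) law.
* **Truncation**: anthropometric and behavioural draws use truncated
  normals (0 and mean ± 3 SD) to avoid non-physical negatives; sampled
  concentrations are capped at the pure-substance limit (10^6^ mg/kg).
* **Totals** are summed per iteration, not per statistic — the 95th
  percentile of a sum is not the sum of 95th percentiles — and each MOE
  pairs with its own dose statistic (the p95 MOE is the smaller).
* **Quantiles**: empirical, linear interpolation between order statistics
  (R type 7); stated because the p95 of 10,000 draws is sensitive to the
  convention.
* **Reproducibility**: one master seed; every parameter draws from its
  own deterministically derived child stream, so results do not depend on
  how many cells exist or the order they are processed; rerunning with
  the same seed is bit-identical.
* **Degeneracy**: with every distribution a point mass, the engine
  collapses onto the deterministic arithmetic to floating-point
  tolerance. Both routes coincide simultaneously when the factor set's
  `use_hours` equals `Dur`/60, since the sampled per-category activity
  duration feeds both routes.

The default age profiles are **placeholders**: the national
exposure-factor handbook behind the original assessment is not public.
They encode realistic magnitudes and the expected contrasts (younger
children mouth more and longer, weigh less, stay home more) under
truncated normals, and are clearly labelled non-authoritative — real
assessments must supply their own profiles. Consequently the
probabilistic engine is validated on structure (degeneracy, seed
stability, ordering between age groups, median-vs-p95 coherence,
replicate stability of the median below 5% relative SD at 10,000
iterations across 20 seeds), never on published percentile values.

## Synthetic survey generator

The surveyed 3345 products are not deposited; the published margins are:
category sizes (605/110/176/785/38/1631), per-(category, chemical)
detection counts, survey-wide counts per chemical (DEHP 264, DINP 141,
DBP 66, DEHA 30, DIBP 14, DEP 10), the co-occurrence structure (387
products with ≥ 1 plasticizer, 286 with exactly one, DEHP in every
multi-plasticizer product except two DBP+DINP shoes, DEP only as a
single chemical in 10 toys) and per-cell maximum concentrations. The
generator reproduces every margin exactly:

* The structural assignment is deterministic and canonical: a fixed,
  blueprint-encoded allocation places 99 DEHP-hosting multi-plasticizer
  products and 136 attached co-detections across categories (the margins
  constrain totals, not the joint table, so any consistent allocation is
  valid; fixing one makes the generator reproducible and
  order-independent). Co-detections are distributed cyclically in
  alphabetical chemical order, which guarantees each hosting product
  carries at least one co-detection and never the same chemical twice.
  `check_blueprint()` verifies all margin arithmetic before generation
  and names the first violated constraint.
* Each cell's maximum concentration is assigned to exactly one product;
  the remaining detected concentrations are drawn from a lognormal
  (log-mean log 2500, log-SD 2.2) truncated to (100 mg/kg, cell
  maximum), chosen so that roughly a quarter of detected values exceed
  1% w/w where the cell maximum allows — exercising both migration-rate
  classes.
* Same seed, same survey, byte for byte; the seed affects only
  concentrations and the cosmetic subcategory labels.

What the generator does **not** emulate: measurement error and matrix
effects (concentrations are "true" values), any real joint distribution
of co-occurring concentrations within a product, within-category
clustering by subcategory, and the shape of the real concentration
distributions (only their maxima and support are constrained; the
lognormal is a stand-in). Passing tests on the synthetic survey therefore
demonstrate that the pipeline reproduces the published *margins and
screening arithmetic*, not that it would reproduce unpublished
distributional detail of the real survey.

## Numerical conventions and degenerate inputs

Internal computation is at full precision; the 2-significant-figure
scientific notation of the published tables is applied only at the
display layer (`format_sci2()`). A chemical absent from a category gives
an empty result, not an error. Zero dose gives an undefined MOE marker.
Non-positive physical inputs fail fast with domain errors. Problem sizes
in the shipped workflow: the full 3345-product survey, 10,000 Monte Carlo
iterations per age group, 20-seed replicate stability — all within
seconds to a minute on one core.

## Known limitations

* The per-chemical dermal unit doses of the original screening table are
  not all recoverable from its single published anchor plus the
  permeability correlations chosen here; only the DEHP dermal column (and
  everything linear in it) is reproduced numerically. The published
  table also contains two rows whose printed components are internally
  inconsistent; nothing is calibrated against those.
* The migration-rate ladder dominates the ingestion estimate; with the
  two-level policy even trace (LOQ/2) content receives the 0.1 mg cm^-2^
  h^-1^ floor, which makes the probabilistic ingestion medians insensitive
  to the chemical and likely conservative by orders of magnitude relative
  to measured migration — precisely the point the sensitivity analysis
  quantifies.
* No cumulative (dose-addition) metric across chemicals; margins are per
  chemical. No mechanistic migration modelling; no multi-layer skin
  model; single daily contact event per category.
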