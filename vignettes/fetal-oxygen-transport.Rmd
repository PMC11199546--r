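---
title: "From MRI signals to fetal oxygen transport: methods and design notes"
author: "fetalox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MRI signals to fetal oxygen transport: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalox)
```

## What this package computes

`fetalox` implements the quantitative chain used in fetal cardiovascular MRI
studies of growth restriction and hypoxaemia: cine phase-contrast (PC) flow
quantification per vessel, blood T2-relaxometry oximetry, assembly of the
measured flows into the fetal shunt circulation, Fick-principle oxygen
delivery and consumption, MRI volumetry-based weights, and a mixed
repeated-measures ANOVA comparing a control and a growth-restricted (FGR)
group across a normoxic and an acutely hypoxic state. Because no scanner
data ship with the package, every stage is exercised on seeded synthetic
phantoms and a virtual cohort whose statistical structure mirrors the study
design (12 control vs 9 FGR fetal sheep, two states per subject).

## Phase-contrast flow

PC-MRI encodes through-plane velocity in the image phase. We fix the
standard mapping $v = (\phi/\pi)\,\mathrm{VENC}$, i.e. the vessel-specific
velocity-encoding limit corresponds to a phase of $\pi$; phases live in
$(-\pi, \pi]$, and the exact boundary $v = \mathrm{VENC}$ maps to $+\pi$.
Default VENCs per vessel are the acquisition values (150 cm/s for AAo, MPA,
DAo and DA; 100 for SVC, carotids and ductus venosus; 80 for the lung
arteries; 50 for the umbilical vein, `default_vencs()`).

Flow integration is the module's core contract: per cardiac phase,
$Q = \sum_{\mathrm{ROI}} v \cdot A_{px}$, converted so that 1 cm/s over
1 cm$^2$ equals 60 mL/min; the reported mean flow is the arithmetic mean of
the 15-phase waveform. Two optional corrections are provided:

* **Static-tissue offset correction** subtracts the per-phase mean velocity
  over a background mask (removes constant eddy-current-like phase offsets
  exactly; idempotent).
* **Aliasing correction** shifts pixels whose sign opposes the ROI-median
  sign and whose magnitude exceeds VENC/2 by $2\,\mathrm{VENC}$. It is
  opt-in because acquisition VENCs are chosen to avoid wraps.

The phantom generator uses a fully developed laminar (parabolic) profile,
which gives a closed-form oracle: a lumen of radius $r$ with centre-line
velocity $v_p$ carries $\pi r^2 v_p / 2$. On a 1 mm grid the discretised
disk matches this within 2% for radii of 8 px and above (0.13% at 10 px);
the residual is pixelation of the lumen boundary, identical in relative
terms for every vessel measured at the same radius — which is why measured
circulations still satisfy flow conservation tightly.

ROI definition for real data is deliberately simple (user mask, or Otsu
threshold on the time-averaged magnitude restricted to a seed box followed
by the largest connected component); lumen segmentation is not the
package's contribution.

## T2 oximetry

Blood T2 rises with oxygen saturation because deoxyhaemoglobin is
paramagnetic. The measurement chain is:

1. **ROI erosion to the central 60%** of the vessel. We interpret "central
   60%" as an *area fraction* selected by distance-transform ranking: mask
   pixels are ranked by distance to the mask boundary and the deepest
   $\max(1, \lfloor 0.6\,n \rfloor)$ pixels are retained (ties broken by
   row-major index). Unlike radius scaling this is well defined for
   non-circular masks; the suite checks it against a brute-force ranking.
2. **Mono-exponential fit** $S(t) = S_0 e^{-t/T_2}$ over the six
   preparation times 32, 64, 96, 128, 160, 192 ms. The default is
   Levenberg–Marquardt least squares on the untransformed signal, seeded
   deterministically from the log-linear (OLS on $\log S$) solution; the
   two agree exactly on noiseless data, and the iterative route weights
   noise correctly at low SNR. A non-decaying series is returned with the
   T2 capped and flagged rather than failing.
3. **Calibration** via the Luz–Meiboom-type quadratic-in-desaturation
   relation $1/T_2 = 1/T_2^{plateau} + K (1-Y)^2$, inverted for the root in
   $[0,1]$. Roots outside by at most 0.02 (noise at the domain edges) are
   clamped and flagged; anything further is an error, since a T2 above the
   plateau is unphysical.

The calibration constants for sheep blood are laboratory-specific and are
**not** published in a reusable numeric form alongside the method, so the
defaults ($T_2^{plateau} = 250$ ms, $K = 0.03$ /ms) are provisional. They
were chosen once to give the dynamic range fetal blood shows at 3 T (T2
roughly 250 ms at full saturation down to ~58 ms at $Y = 0.3$): with a much
smaller $K$ the desaturation term would be a sub-percent perturbation of
$1/T_2^{plateau}$ and the inversion becomes ill-conditioned near full
saturation. An optional linear haematocrit modifier of $K$ is provided.
Every run manifest tags these constants as provisional.

Motion correction is out of scope; a rigid ROI re-centring hook exists in
spirit via user-supplied per-image masks, but non-rigid co-registration is
deliberately not reimplemented.

## Circulation assembly

Measured flows combine by the standard rules: $PBF = LPA + RPA$,
$RVCO = DA + PBF$, $LVCO = AAo$ (coronary flow excluded),
$CVO = RVCO + LVCO$, combined carotid flow $= CCA_l + CCA_r$. Two flows are
not directly measurable and are derived — and flagged as estimates in every
output:

* **Foramen ovale**: $FO = LVCO - PBF$, i.e. left-heart inflow minus
  pulmonary venous return. This is the only derivation consistent with the
  measured-vessel list once coronary flow is excluded from LVCO.
* **Lower-trunk flow**: $DAo - UV$, descending-aortic flow minus placental
  return.

Distribution is expressed as % of CVO. Conservation is checked two ways:
the anatomical identity $MPA = DA + PBF$ (relative discrepancy; absolute
when MPA is zero) and the CVO partition
$DA + PBF + FO + \text{pulmonary venous return}(= PBF)$, whose percentage
shares must total 100. Division by a zero CVO raises an error rather than
propagating NaN into group statistics.

## Oxygen transport

Units are fixed package-wide: haemoglobin g/L, flows mL/min, blood oxygen
content mL O$_2$/L, so delivery and consumption in mL O$_2$/min carry a
$/1000$ factor that the compact textbook equations leave implicit. With
1.36 mL O$_2$ bound per gram of haemoglobin:

$$\mathrm{DO_2^{fetal}} = 1.36\,[\mathrm{Hb}]\,Y_{UV}\,Q_{UV}/1000
\qquad
\mathrm{VO_2^{fetal}} = 1.36\,[\mathrm{Hb}]\,(Y_{UV}-Y_{DAo})\,Q_{UV}/1000$$

and the cerebral pair substitutes $Y_{AAo}$, $Y_{SVC}$ and the combined
carotid flow. The extraction fraction is
$(Y_{in}-Y_{out})/Y_{in}$ over the same vessel pairs the consumption
equations use — the only definition under which a fallen delivery, a risen
extraction fraction and an unchanged consumption can coexist, which is the
physiology the cerebral circulation shows under acute hypoxia. Negative
arteriovenous differences are flagged, never clipped: they indicate
oximetry inconsistency worth surfacing. Haemoglobin is taken per state by
default (a scan-mean switch is a one-line override when building the
cohort table), and per-kg normalisation divides by the volumetry-derived
weight in kg.

## Volumetry

Label maps use 0/1/2 for background/body/brain with the brain inside the
body, so fetal volume counts both labels — the premise behind reporting
brain weight relative to body weight. Volume-to-weight conversion factors
are mandatory configuration with provisional soft-tissue-density defaults
(1.03/1.04 g/mL) because the literature values are laboratory-specific.

## The statistical layer

The group comparison is a mixed (split-plot) two-way ANOVA: group
(control/FGR, unbalanced 12 vs 9) between subjects, state
(normoxia/hypoxia) within subjects. The between stratum tests group against
subject-within-group variation — with a single between factor, Type I and
Type III sums of squares coincide, so the unbalance is handled without
ambiguity. The within stratum tests state and group × state against the
state × subject-within-group residual; with complete two-state data the
cell frequencies are proportional, making the weighted (classical
split-plot) decomposition orthogonal. Two within levels mean sphericity
holds trivially; no epsilon correction is applied or needed. The
implementation is direct sums-of-squares arithmetic and is tested to
$10^{-9}$ against an independent `aov` + `Error(subject)` oracle on random
balanced and unbalanced designs.

Pairwise comparisons are fixed to the four the figures imply — group within
each state (unpaired, pooled variance) and state within each group
(paired) — Bonferroni-adjusted with $m = 4$. One-state variables
(uterine-artery flow, weights) use Student's unpaired t-test, and
Shapiro–Wilk screens normality per cell.

## The synthetic cohort: what it emulates, and what it does not

The generator draws every variable from a group × state normal
distribution with a subject-level random intercept carrying half the
variance (so the two states of a subject correlate at ~0.5), truncated to
physical ranges by rejection sampling on the whole subject pair — rejection
rather than clipping avoids point masses at 0 or 1. Cells anchored to
published study-design values: arterial (AAo) saturation
(58.5 ± 7.5% control / 47.4 ± 7.3% FGR in normoxia, 29 ± 7.6 / 27.4 ± 6.1%
in hypoxia), haemoglobin (98 ± 9 g/L control-normoxia and the matching
cells) and heart rate (140 ± 10 bpm and matching cells). **Per-vessel flow
means and SDs are available only as figures, not numbers; the defaults here
are plausible values for ~118-day fetal sheep (e.g. CVO ≈ 540 mL/min for a
1.25 kg control fetus) and are flagged provisional in the config and the
run manifest.** They encode the study's direction of effects: raised ductus
venosus and foramen ovale flow in FGR in both states, reduced pulmonary
blood flow in FGR during normoxia only, saturations falling under acute
hypoxia with a state-invariant AAo−SVC difference (the cerebral circulation
maintaining consumption by raising extraction), and a widened AAo−MPA
saturation gap under hypoxia. Each effect has a toggle so null behaviour
can be simulated.

Generated circulations are always self-consistent — MPA is constructed as
DA + LPA + RPA and the programmed foramen-ovale flow recorded — which is
what makes the conservation and shunt-recovery checks exact.

What the generator does *not* emulate: k-space artefacts, gating jitter,
eddy currents beyond a constant phase offset, motion, T1/T2* contamination
of the T2 preparation, non-normal biological variation, and any
maternal-side physiology. Passing tests therefore demonstrate that the
computational chain is correct and well conditioned under the assumed
signal models — not that the acquisition itself is accurate on real
scanners.

## Numerical choices and degenerate inputs

* Phase wrapping maps the boundary to $+\pi$ exactly, so $v=\mathrm{VENC}$
  is representable.
* The T2 fit caps at $10^5$ ms with an `at_bound` flag for non-decaying
  input; the log-linear seed makes the iterative fit deterministic.
* The calibration inversion clamps roots within 0.02 of $[0,1]$ (flagged)
  and errors beyond; $K = 0$ with $T_2 \ne T_2^{plateau}$ is unidentifiable
  and errors.
* `derive_flows` propagates NA for vessels that are absent (strict mode
  errors, naming the vessel); a zero CVO errors on the distribution.
* One master seed derives per-stage substreams by a deterministic label
  hash (`derive_seed`), keeping every derived seed below $2^{31}$; reruns
  are byte-identical.

## Problem sizes used by the checks

The shipped validation uses phantom radii 6–15 px on ~29 px grids with 15
cardiac phases; 200-replicate noise studies for flow; 1000-replicate T2
recovery at SNR 50; 5000 null cohorts for ANOVA type-I calibration; 1000
replicates per interaction effect size for power; and 30 replicate full
cohorts for the direction-of-effect pattern. The demo imaging pipeline
runs 3 subjects per group; the tabular cohort analyses run the full 12 vs
9 design.

## Known limitations

* The FO and lower-trunk derivations cannot be verified against a direct
  measurement; they remain flagged estimates by construction.
* Calibration constants, conversion factors and vessel flow distributions
  are provisional configuration, not ground truth; quantitative use
  requires laboratory values.
* The ANOVA covers exactly the two-factor mixed design (any number of
  levels, complete within-subject data); there is no mixed-model/REML
  machinery for missing states.
* ROI handling is 2-D per slice; no volumetric flow, no non-rigid motion
  correction, no dissolved-oxygen term in the Fick equations.
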