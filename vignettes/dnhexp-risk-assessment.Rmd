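---
title: "From urinary MnHexP to a provisional TDI: methods behind phthalrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From urinary MnHexP to a provisional TDI: methods behind phthalrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phthalrisk)
```

phthalrisk implements a complete desk-scale risk-assessment chain for
di-n-hexyl phthalate (DnHexP), a reproductive toxicant that keeps turning up
as a contaminant in consumer products and, via its monoester metabolite
mono-n-hexyl phthalate (MnHexP), in human urine surveys. The chain has five
stages, each usable on its own: reverse dosimetry, exposure-scenario
modelling, forward dosimetry, benchmark-dose (BMD) modelling, and derivation
of a tolerable daily intake (TDI) with risk characterisation. This vignette
explains the models, their assumptions, the tunable parameters and the
numerical choices; the package's tests compute every empirical claim made
here.

## Reverse and forward dosimetry

A spot-urine metabolite concentration $C_U$ (µg/L) is converted to a daily
intake of the parent diester (µg/kg bw/day) by

$$DI = C_U \cdot \frac{Q_U}{f_{UE}} \cdot \frac{MW_p}{MW_m},$$

where $Q_U$ is the body-weight-adjusted urinary output rate (0.025 L/kg
bw/day for adults — 1.5 L/day at 60 kg — and 0.030 for 1–3-year-old
children), $f_{UE} = 0.69$ is the molar fraction of an oral dose excreted in
urine as the monoester within 24 h (determined experimentally for the DBP
monoester, which shares the linear alkyl side chain), and $MW_p/MW_m =
334.45/250.29$ converts metabolite mass back to parent mass. The inverse map
(forward dosimetry),

$$C_U = SED \cdot \frac{MW_m}{MW_p} \cdot \frac{f^{SED}_{UE}}{Q_U},$$

predicts the urine level corresponding to a systemic exposure dose.
$f^{SED}_{UE}$ defaults to $f_{UE}$ (oral bioavailability close to 1) but is
kept as a separate field because route-dependent excretion fractions are
plausible. The two maps are exact inverses whenever $f^{SED}_{UE} = f_{UE}$,
a property the test suite checks to machine precision.

Assumptions worth keeping in mind: steady-state intake (no time-course
modelling of the 3–8 h elimination half-life), no creatinine adjustment, and
a single $Q_U$ per population. High percentiles of spot-urine data therefore
overestimate long-term intake; medians are the robust statistic.

**Censoring.** Concentrations below the limit of quantification (LOQ) must
be substituted before summarising. The underlying survey does not state its
substitution rule, so the package offers four policies — `loq_half`
(default), `loq_sqrt2`, `zero`, `exclude` — selected per call and recorded
in the summary output. Percentiles use linear interpolation between order
statistics (`quantile()` type 7); the convention is fixed because reported
percentiles depend on it. All arithmetic is at full floating precision;
rounding (3 significant figures, 2 for scenario SEDs) happens only at report
rendering.

## Exposure scenarios

Four consumer-product scenarios are parameterised after the SCCS Notes of
Guidance. For dermal or oral contact,
$SED = m_{prod} \cdot c \cdot f_{abs} / BW$; with $m_{prod}$ in g, $c$ in
mg/kg and $BW$ in kg this is numerically in µg/kg bw/day. Spray inhalation
follows the three-step 2-Box model: airborne amount
$a_{expo} = m_{prod} c f_{air}$, inhaled amount
$a_{inh} = a_{expo} r_{inh} (t_A/V_A + t_B/V_B)$ with a 1000-L breathing
zone (2 min) and a 10 000-L room (10 min) without air exchange, and
$SED = a_{inh} f_{ret} / BW$, conservatively treating the swallowed
non-respirable fraction as systemically available. Contact with migrating
plasticiser uses $SED = A_{skin} M_R t_{contact} f_{abs} / BW$.

Two parameter choices deserve comment:

* **Dermal absorption fraction.** The assessment literature contains an
  internal inconsistency ("0.05 %" in one passage, 0.05 in the parameter
  table); only $f_{abs} = 0.05$ (5 %) reproduces any of the worked values,
  so 0.05 is the package default. It is itself conservative — human dermal
  absorption is more plausibly around 1.5 %.
* **Migration rate.** $M_R = 0.007$ µg/cm²/h is adopted as a constant
  because the underlying 138-product migration dataset is external; the
  package ships `fit_migration_rate()` (through-origin OLS by default,
  intercept optional) so the same estimate can be re-derived when such data
  are available, and `M_R` is always directly overridable.

Child cosmetic scenarios reuse the adult product-side amounts (same ingested
lip-balm amount, same inhaled spray amount) with a 10-kg body weight; the
child sunscreen amount is the 95th-percentile application rate of 0.971 g/kg
bw/day. **Aggregation** across pathways is an arithmetic sum within one
population. The headline aggregates (0.2574 adult, 0.885 child at 16 mg/kg)
are sums of the pathway SEDs at their displayed 2-significant-figure
precision — that is how the original aggregation was performed — so the
report layer aggregates displayed values and keeps the full-precision sum
(0.2576, 0.8824) alongside. The report's urine column is likewise derived
from the displayed SED so that each row is internally consistent.

One reported value is *not* reproduced on purpose: applying forward
dosimetry to the sandals SED of 0.048 µg/kg bw/day with the child
$Q_U = 0.030$ gives 0.83 µg/L, not the 1.48 µg/L printed in the source
table; the report computes the equation faithfully and flags the
discrepancy here rather than matching the printed number. Similarly, the
printed child aggregate urine level (18.3 µg/L) corresponds to the adult
rather than the child $Q_U$; the package reports 15.2.

## Benchmark-dose modelling

The point of departure is a 20 % decrease in ex vivo foetal testosterone
production, a well-established key event of C4–C6 phthalate reproductive
toxicity. The benchmark response comes from effect-size theory: an endpoint
with an $M$-fold maximum dynamic range has equivalent small-amplitude effect
size $ES = M^{1/8}$, i.e. 1.223–1.334 for the five- to tenfold testosterone
decrease, an 18–25 % band; 20 % is the expert-judgement choice within it.

Litter-level responses (litter = statistical unit) from two experiments
covering doses 0–625 mg/kg bw/day are pooled; pooling is justified by a
Welch two-sample test on the two control groups
(`welch_pooling_check(7.73, 0.96, 10, 7.47, 2.08, 11)` gives p ≈ 0.71), and
an experiment covariate is deliberately not modelled.

The original analysis used a Bayesian model-averaging web tool. phthalrisk
deliberately does not reproduce that posterior; it ships an independent
frequentist engine of similar spirit, suitable for desk-scale work:

* **Model suite:** four decreasing continuous models — exponential and Hill,
  each in 3- and 5-parameter form — fitted to log responses by maximum
  likelihood with lognormal errors. The background level and the error SD
  are profiled out analytically, so each fit optimises only 2–3 shape
  parameters (`nlminb`, multiple starts).
* **Scale handling:** doses are normalised internally by the maximum dose,
  making the optimiser bounds scale-free; BMD estimates are then exactly
  equivariant under dose rescaling, and the relative BMR definition makes
  them invariant under response rescaling. Both are property-tested.
* **Averaging:** AIC-based pseudo-Bayesian weights,
  $w_i \propto \exp(-\Delta AIC_i/2)$; the model-averaged BMD is the
  weight-geometric mean of per-model BMDs.
* **Uncertainty:** a model-averaged parametric bootstrap (default 1000
  replicates, 200 in the packaged examples; seed mandatory). Each replicate
  simulates from one fitted model drawn by its weight, refits the suite and
  records the refit averaged BMD; BMDL/BMDU are the 5th/95th percentiles.
* **Degeneracy:** if the weighted fitted decrease at the top dose does not
  reach the BMR (flat or increasing data), the BMD is reported as undefined
  rather than extrapolated; shape exponents are bounded to [0.25, 8];
  bootstrap replicates without a defined BMD are dropped with a warning
  when they exceed half the replicates.

On synthetic data with the two-experiment design (21 pooled control litters,
8–10 per dose group, control geometric mean 7.7, litter CV 20 %, true
BMD$_{20}$ = 21 mg/kg bw/day) the bootstrap interval covers the truth in at
least 90 % of 50 replicate simulations — the package's acceptance property
for this stage, chosen because the published Bayesian interval itself
(BMD 21.0, credible interval 14.9–30.0) cannot be matched exactly without
the original tool and per-litter data. The packaged synthetic fixture
(`testosterone_litter_synthetic.csv`, generated by `gen_dose_response()`
with seed 101) yields a fitted BMD inside that published interval.

The published analysis states BMDL$_{20}$ = 14.9 mg/kg bw/day where the TDI
is derived but uses 14.7 in the margin-of-safety arithmetic; both values are
explicit, independent config entries (`pod.bmdl` and `pod.pod_for_mos`),
never silently coupled.

## Approximate probabilistic TDI

The WHO/IPCS approximate probabilistic approach treats every uncertainty
source as a lognormal and combines them in closed form (log medians add, log
variances add, independence assumed):

1. **PoD uncertainty:** lognormal with P05 = BMDL = 14.9 and P95 = BMDU =
   30.0 mg/kg bw/day (median $\sqrt{14.9 \times 30} \approx 21.1$).
2. **Interspecies body-size scaling:** dose-rate scaling by
   $(BW_{rat}/BW_{human})^{0.3}$ (0.2 kg → 60 kg: factor ≈ 0.181), with
   exponent uncertainty giving P95/P50 = $(BW_h/BW_a)^{0.04}$.
3. **Interspecies TK/TD residual:** P50 = 1, P95/P50 = 3 (divides).
4. **Intraspecies variability** protecting the 1 % most sensitive
   individuals: P50 = 9.7, P95/P50 = 4.3 (divides).

Items 2–4 are the published WHO (2017) approximate defaults; the exact
quantile table the original assessors used is not public, so these ship as
an editable, versioned YAML config (`af_who2017.yaml`) with each number
sourced in comments, and the reproduction of the published 63–2780 µg/kg
bw/day interval is a configuration-validation test with a 10 % tolerance
rather than a hard-coded result. With the shipped defaults the 90 % interval
of the maximum safe daily intake is 60.5–2563 µg/kg bw/day (−4 % / −8 %
against the published bounds). The TDI is the interval's lower bound. The
deterministic alternative — BMDL divided by an overall assessment factor of
100 — gives 147 µg/kg bw/day from the 14.7 PoD, confirming that the
probabilistic route is the more conservative of the two.

A closed-form-versus-Monte-Carlo test ($10^6$ draws) verifies the lognormal
combination, and monotonicity properties (raising the BMDL never lowers the
TDI; widening any component never narrows the interval) are tested directly.

## Risk characterisation

Three comparators: percent of TDI ($100 \cdot E / TDI$), margin of safety
($PoD / E$ with the PoD in µg/kg bw/day), and DEHP equivalents
($E \times 0.79$, where $0.79 = 50/63$ is the potency weighting factor
against the EFSA group TDI of 50 µg DEHP eq/kg bw/day). They satisfy the
consistency identity $(\%TDI/100) \cdot MoS = PoD/TDI$, which is
property-tested. `build_report()` assembles the intake and scenario tables
with metadata (seed, config hash, package version) and regenerates
byte-identically from identical inputs.

## Synthetic data

The generators exist so every stage is testable without restricted survey
data; they emulate printed summary statistics, not raw datasets.

* **Urine concentrations:** lognormal (the standard family for
  biomonitoring concentrations; the survey prints only quantiles),
  quantile-matched to median 0.56 and P75 1.93 µg/L, giving
  sdlog ≈ 1.83. The default LOQ of 0.335 µg/L is the 39th percentile of
  that distribution, chosen once so that ≈ 61 % of draws are quantifiable,
  matching the printed detection fraction; the true analytical LOQ is not
  public. What these defaults do *not* emulate: within-child repeated
  measures, seasonal or cohort structure, or secondary metabolites — so
  passing tests say nothing about those features of real data.
* **Dose-response:** litter responses lognormal around a decreasing
  exponential curve with asymptote fraction 0.1 (a tenfold maximum
  decrease, the midpoint of the reported five–tenfold range), control
  geometric mean 7.7, CV 20 % (consistent with the printed control SDs),
  and the rate solved so the true BMD at the stated BMR is exact.
* **Product concentrations:** censored lognormal, n = 57, rescaled so the
  sample maximum equals the printed survey maximum of 16 mg/kg.

All generators require a seed, restore the caller's RNG state, and
regenerate bit-identically.

## Problem sizes and limitations

The packaged tests run the BMD coverage study at 50 replicates × 200
bootstrap refits and the Monte-Carlo oracle at $10^6$ draws — sizes chosen
so the whole suite completes in a few minutes on one core while leaving the
Monte-Carlo error well below the asserted tolerances. Known limitations:
no pharmacokinetic time-course or creatinine adjustment; no aerosol
particle-size or room air-exchange physics beyond the static 2-Box model;
no covariate or historical-control modelling in the BMD stage; no cumulative
multi-phthalate mixture assessment beyond the single-substance DEHP
equivalent; and the approximate (not full Monte-Carlo) probabilistic
method, whose closed-form convenience rests on the independence of the
lognormal components.

## A worked end-to-end run

```{r}
cf <- load_config()
urine <- gen_urine_dataset(n = 250, seed = cf$seed)
run <- run_pipeline(cf, urine = list(daycare = urine), quiet = TRUE)
run$tdi
run$report
```
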