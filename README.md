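# phthalrisk

An R package implementing a complete, reproducible risk-assessment chain for
**di-n-hexyl phthalate (DnHexP)**, a reproductive toxicant found as a
contaminant in sunscreen, other cosmetics and plastic consumer goods, and
detectable in human urine as its monoester metabolite **mono-n-hexyl
phthalate (MnHexP)**. It is written for regulatory toxicologists and
exposure scientists who need to go from biomonitoring tables or product
surveillance data to a defensible health-based comparison.

The chain, each stage usable on its own:

1. **Reverse dosimetry** — daily intake from a urinary concentration:
   `DI = C_U · (Q_U / f_UE) · (MW_p / MW_m)`, with `Q_U` = 0.025 (adult) or
   0.030 (child) L/kg bw/day, `f_UE` = 0.69, MW 334.45/250.29 g/mol.
2. **Exposure scenarios** — systemic exposure doses (SED) for dermal/oral
   product contact (`SED = m_prod · c · f_abs / BW`), spray inhalation via
   the SCCS 2-Box model, and dermal contact with migrating plasticiser
   (`SED = A_skin · M_R · t_contact · f_abs / BW`), with the full parameter
   library packaged.
3. **Forward dosimetry** — predicted urine levels from SEDs (the inverse of
   stage 1), for comparing modelled scenarios against measured urine data.
4. **Benchmark-dose modelling** — litter-level continuous BMD analysis of
   foetal testosterone data: exponential + Hill families with lognormal
   errors, AIC-weighted model averaging, parametric-bootstrap BMDL/BMDU,
   and the effect-size rule `ES = M^(1/8)` that fixes the 20 % benchmark
   response.
5. **TDI and risk characterisation** — the WHO/IPCS approximate
   probabilistic derivation of a tolerable daily intake (lognormal
   uncertainty algebra over PoD, allometric scaling, interspecies residual
   and intraspecies variability), the deterministic PoD/100 alternative,
   percent-of-TDI, margins of safety and DEHP-equivalent potency weighting.

Synthetic-data generators (urine surveys, litter-level dose-response
designs, product-concentration surveys) make the whole chain testable
without access to restricted survey data.

## Worked example

```r
library(phthalrisk)

cf <- load_config()                               # packaged defaults
urine <- gen_urine_dataset(n = 250, seed = cf$seed)  # synthetic child survey
run <- run_pipeline(cf, urine = list(daycare = urine), quiet = TRUE)
run$tdi
#> Approximate probabilistic TDI: 60.5 ug/kg bw/day
#>   90% interval of the maximum safe dose: 60.5 - 2.56e+03
#>   deterministic comparison (PoD / overall AF): 149
run$report
#> Risk characterisation report
#>   TDI 60.5 ug/kg bw/day, PoD 1.47e+04 ug/kg bw/day
#>
#> Intake summary:
#>   cohort statistic intake_ugkgday percent_of_tdi   n loq_policy
#>  daycare       50%         0.0296          0.049 250   loq_half
#>  daycare       95%         0.7860          1.300 250   loq_half
#>  daycare   maximum         6.8500         11.000 250   loq_half
#>
#> Scenario SEDs and predicted urine levels:
#>  population         scenario            route sed_display urine_ugL ...
#>       adult  sunscreen_adult           dermal      0.2400    4.9600
#>       adult   lip_balm_adult             oral      0.0150    0.3100
#>       adult pump_spray_adult       inhalation      0.0024    0.0496
#>       child  sunscreen_child           dermal      0.7800   13.4000
#>       ...
#>
#> Aggregated SEDs:
#>  population aggregated_sed_ugkgday aggregated_sed_full urine_ugL ...
#>       adult                 0.2574              0.2576      5.32
#>       child                 0.8850              0.8824     15.20
```

Reading the output: the TDI of ~60 µg/kg bw/day is the lower bound of the
90 % interval for the maximum safe daily intake derived from the BMDL/BMDU
pair (14.9/30.0 mg/kg bw/day) by the approximate probabilistic method — more
conservative than the deterministic PoD/100 value of 149. The synthetic
survey's median intake (~0.03 µg/kg bw/day) sits near 0.05 % of the TDI,
and even the worst scenario SEDs stay 4 orders of magnitude below the PoD
(margins of safety in the ten-thousands at the measured 16 mg/kg product
contamination).

Individual stages are plain functions:

```r
reverse_dosimetry(46.18, population_parameters("child"))$daily_intake
#> [1] 2.682958
sed(scenario_library(300)$sunscreen_adult)$sed
#> [1] 4.5
fit_bmd_models(read_dose_response(system.file("extdata",
  "testosterone_litter_synthetic.csv", package = "phthalrisk")),
  bmr = 0.20, n_bootstrap = 200, seed = 42)
#> Model-averaged BMD at BMR 20% decrease
#>   BMD  19.1   BMDL 15.1   BMDU 29  (mg/kg bw/day)
```

See `vignette("dnhexp-risk-assessment")` for the models, their assumptions
and every numerical choice.

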