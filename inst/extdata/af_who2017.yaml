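# Default uncertainty quantiles for the WHO/IPCS approximate probabilistic
# hazard characterisation (WHO/IPCS 2017, Guidance document on evaluating
# and expressing uncertainty in hazard characterization, 2nd ed.; see also
# Chiu & Slob 2015, Environ Health Perspect 123:844-850).
#
# Every component is a lognormal. Ratios refer to P95/P50.
version: who-ipcs-2017-approximate
allometric:
  # interspecies body-size scaling of dose rates per kg bw: exponent 0.7,
  # i.e. median dose-scaling factor (bw_animal/bw_human)^0.3; uncertainty in
  # the exponent gives P95/P50 = (bw_human/bw_animal)^0.04
  exponent: 0.7
  exponent_uncertainty_p95_ratio_power: 0.04
interspecies_tktd:
  # residual interspecies TK/TD differences beyond allometry
  p50: 1.0
  p95_ratio: 3.0
intraspecies:
  # human variability: ratio between the median human and the individual at
  # the protected incidence (default 1% of the population)
  incidence: 0.01
  p50: 9.7
  p95_ratio: 4.3
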