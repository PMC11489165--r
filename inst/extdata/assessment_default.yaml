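# Default assessment configuration for the DnHexP/MnHexP risk pipeline.
# Kinetic parameters: adults 1.5 L urine/day at 60 kg bw; children 1-3 y;
# f_UE 0.69 determined for the DBP monoester (shared linear side chain).
populations:
  adult:
    q_u: 0.025        # L/kg bw/day
    f_ue: 0.69
    mw_parent: 334.45 # g/mol, DnHexP
    mw_metabolite: 250.29 # g/mol, MnHexP
  child:
    q_u: 0.030
    f_ue: 0.69
    mw_parent: 334.45
    mw_metabolite: 250.29
scenarios:
  concentration_mgkg: 16   # maximum found across 57 sunscreen samples
  migration_rate: 0.007    # ug/cm^2/h, pooled migration regression
pod:
  bmdl: 14.9          # mg/kg bw/day, BMD credible-interval lower bound
  bmdu: 30.0          # mg/kg bw/day, upper bound
  pod_for_mos: 14.7   # mg/kg bw/day, PoD used for margins of safety
tdi:
  coverage: 0.90
  bw_animal: 0.2      # kg, rat
  bw_human: 60        # kg
  deterministic_af: 100
  af_config: ~        # null -> packaged WHO/IPCS 2017 defaults
loq_policy: loq_half
reference:
  group_tdi_dehp: 50  # ug DEHP equivalents/kg bw/day
seed: 17
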