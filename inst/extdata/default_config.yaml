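# Default synthetic pipeline configuration: a 24-sample screen over 500
# 100-nt windows (50 promoters of 10 windows), with 8 planted monotone DMRs
# clustered into one promoter, and a 175-subject validation cohort.
seed: 1
simulation:
  n_regions: 500
  n_true_dmrs: 8
  dmr_placement: clustered
  dmr_effect: 0.25
  monotone: true
  noise_sd: 0.03
  probe_noise_sd: 0.1
thresholds:
  robust_p: 0.02
  mw_extreme_p: 0.02
  mw_adjacent_p: 0.01
  abs_diff: 0.20
tiers: [sex, sex_maternal]
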