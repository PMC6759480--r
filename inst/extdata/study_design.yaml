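# rupvitro design config, schema rupvitro-design/1
#
# Reference three-supplement in vitro rumen fermentation trial bundled with
# the package: soybean meal (SBM), whey protein (WHEY) and yeast-derived
# microbial protein (YMP) dosed at three isonitrogenous levels on a
# grass-silage + compound-feed basal substrate in 40-mL batch cultures.
# BCAA amounts are mmol introduced per vessel with the supplement dose
# (reported to 3 decimals, hence the 5% cross-check tolerance against any
# composition-derived amounts).
schema: rupvitro-design/1
vessel_volume_mL: 40
replicates_per_time: 6
sampling_times_h: [4, 10, 24]
control_id: Control
basal:
  - {name: grass silage, dm_mg: 400, cp_frac: 0.16}
  - {name: compound feed, dm_mg: 400, cp_frac: 0.19}
supplements:
  - name: SBM
    cp_frac: 0.542
    doses:
      - {level: low, dose_mg_dm: 13.5, bcaa_mmol: {Val: 0.003, Ile: 0.002, Leu: 0.004}}
      - {level: med, dose_mg_dm: 75.3, bcaa_mmol: {Val: 0.016, Ile: 0.013, Leu: 0.023}}
      - {level: high, dose_mg_dm: 290, bcaa_mmol: {Val: 0.062, Ile: 0.052, Leu: 0.088}}
  - name: WHEY
    cp_frac: 0.892
    doses:
      - {level: low, dose_mg_dm: 8.22, bcaa_mmol: {Val: 0.004, Ile: 0.004, Leu: 0.006}}
      - {level: med, dose_mg_dm: 45.7, bcaa_mmol: {Val: 0.023, Ile: 0.022, Leu: 0.036}}
      - {level: high, dose_mg_dm: 176, bcaa_mmol: {Val: 0.088, Ile: 0.085, Leu: 0.139}}
  - name: YMP
    cp_frac: 0.458
    doses:
      - {level: low, dose_mg_dm: 16.0, bcaa_mmol: {Val: 0.003, Ile: 0.002, Leu: 0.003}}
      - {level: med, dose_mg_dm: 89.0, bcaa_mmol: {Val: 0.017, Ile: 0.012, Leu: 0.019}}
      - {level: high, dose_mg_dm: 343, bcaa_mmol: {Val: 0.065, Ile: 0.047, Leu: 0.074}}
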