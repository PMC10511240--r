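# Example configuration for run_quant_pipeline(): the reference protocol
# values, written out explicitly.
n_cells: 1.0e+07
extract_volume_ul: 20
aliquot_volume_ul: 15
apply_recovery: true
response_ratio: 1.0
mt_tolerance: 0.2
include_ip6: false
recoveries:
  1-IP7: 0.89
  5-IP7: 0.90
  1,5-IP8: 0.75
  IP6: 0.90
spike_conc_um:
  1,5-IP8: 2
  5-IP7: 10
  1-IP7: 10
  IP6: 40
spike_volume_ul: 0.75
v_cell_fl: 42
f_nucleus: 0.08
f_organelles: 0.18
exclude_nucleus: false
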