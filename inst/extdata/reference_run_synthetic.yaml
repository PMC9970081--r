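# SYNTHETIC stand-in for the running HITL reference profile (3.0 m/s,
# N = 12). Published values: the key-point min/max ranges (percent stance)
# and the 8.8% onset fraction. Mean timings are range midpoints; the peak
# torque and per-subject sets are synthetic constructions.
study: synthetic running HITL reference
gait_type: run
phase_kind: stance
onset_fraction: 0.088
mean:
  onset_percent: 27.05
  peak_percent: 72.0
  offset_percent: 95.95
  peak_torque: 0.67
  onset_torque_fraction: 0.088
range:
  onset: [13.6, 40.5]
  peak: [64.5, 79.5]
  offset: [93.9, 98.0]
subjects:
  - {onset_percent: 13.6, peak_percent: 64.5, offset_percent: 93.9, peak_torque: 0.55, onset_torque_fraction: 0.088}
  - {onset_percent: 22.0, peak_percent: 70.0, offset_percent: 95.0, peak_torque: 0.63, onset_torque_fraction: 0.088}
  - {onset_percent: 32.0, peak_percent: 74.0, offset_percent: 97.0, peak_torque: 0.72, onset_torque_fraction: 0.088}
  - {onset_percent: 40.5, peak_percent: 79.5, offset_percent: 98.0, peak_torque: 0.78, onset_torque_fraction: 0.088}
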