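# SYNTHETIC stand-in for the walking HITL reference profile (treadmill
# walking at 1.25 m/s, N = 11). Only the key-point min/max ranges and the
# mean offset (62.7% gait) were published; the mean onset/peak timings here
# are the range midpoints, the peak torque is a realistic synthetic choice,
# and the per-subject parameter sets and EO speed anchors are synthetic
# constructions spanning the published ranges.
study: synthetic walking HITL reference
gait_type: walk
phase_kind: gait
onset_fraction: 0.039
toe_off_percent: 62.7
mean:
  onset_percent: 27.35
  peak_percent: 50.6
  offset_percent: 62.7
  peak_torque: 0.55
  onset_torque_fraction: 0.039
range:
  onset: [17.2, 37.5]
  peak: [48.4, 52.8]
  offset: [59.0, 64.7]
subjects:
  - {onset_percent: 17.2, peak_percent: 48.4, offset_percent: 59.0, peak_torque: 0.40, onset_torque_fraction: 0.039}
  - {onset_percent: 24.0, peak_percent: 50.0, offset_percent: 62.0, peak_torque: 0.50, onset_torque_fraction: 0.039}
  - {onset_percent: 31.0, peak_percent: 51.5, offset_percent: 64.0, peak_torque: 0.62, onset_torque_fraction: 0.039}
  - {onset_percent: 37.5, peak_percent: 52.8, offset_percent: 64.7, peak_torque: 0.68, onset_torque_fraction: 0.039}
eo_anchors:
  - {speed: 0.75, onset_percent: 26.0, peak_percent: 49.0, offset_percent: 61.5, peak_torque: 0.40, onset_torque_fraction: 0.039}
  - {speed: 1.25, onset_percent: 27.35, peak_percent: 50.6, offset_percent: 62.7, peak_torque: 0.55, onset_torque_fraction: 0.039}
  - {speed: 1.75, onset_percent: 28.5, peak_percent: 52.0, offset_percent: 63.5, peak_torque: 0.70, onset_torque_fraction: 0.039}
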