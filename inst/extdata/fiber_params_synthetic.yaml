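# Default fiber and controller parameters.
#
# PROVENANCE: the slow/fast hyperbola constants M and D below are SYNTHETIC
# defaults chosen by this package (arbitrary ATP-rate units): fast-twitch
# fibers get a higher asymptotic rate and reach half of it at a higher
# shortening velocity (smaller D). Absolute rate units do not affect profile
# shape because the peak-matching scale factor absorbs them. Replace with
# measured single-fiber ATPase constants when available.
#
# The composition (0.8 slow / 0.2 fast soleus), eccentric corrections
# (1/2.7 velocity, 1/3.6 force), moment arm (4.2 cm) and onset fractions
# (3.9% walk, 8.8% run) are the published modelling constants.
slow:
  M: 1.0
  D: 4.0
fast:
  M: 3.0
  D: 1.5
composition:
  r_slow: 0.8
  r_fast: 0.2
corrections:
  velocity_factor: 0.37037037037037035   # 1/2.7
  force_factor: 0.2777777777777778       # 1/3.6
moment_arm: 0.042
onset_fraction:
  walk: 0.039
  run: 0.088
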