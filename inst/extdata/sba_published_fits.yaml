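# Published linear dose-response parameter sets for the swim bladder area
# endpoint (PFOS index chemical, 6:2 FTS co-chemical). Units: a, R0 in mm^2;
# b in mm^2 per ug/L. Used by the `rp` and `mixture` subcommands.
fits:
  index:        # PFOS, component study
    a: 0.04563
    b: -6.45e-6
    R0: 0.0637
  co:           # 6:2 FTS, component study
    a: 0.05499
    b: -5.60e-7
    R0: 0.0594
  index_alone:  # PFOS, component study (alias for the mixture workflow)
    a: 0.04563
    b: -6.45e-6
    R0: 0.0637
  index_mix:    # PFOS component of the binary-mixture study
    a: 0.05218
    b: -1.57e-5
    R0: 0.0529
  co_mix:       # 6:2 FTS component of the binary-mixture study
    a: 0.05250
    b: -1.39e-6
    R0: 0.0529
grid: [0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
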