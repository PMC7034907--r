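# Reproducible synthetic demo: mummy-like phantom generated at 146.1 keV,
# calibrated against its bone-like reference region and classified.
mode: synthetic
synthetic:
  energy: 146.1
seed: 42
beamline: body_24um
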