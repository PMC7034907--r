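# Values as read off a real scan: cortical-bone reference attenuation plus
# the average/maximum attenuation of the segmented mineral inclusions.
mode: measured
measured:
  reference_mu: 0.274
  average: 0.297
  maximum: 0.334
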