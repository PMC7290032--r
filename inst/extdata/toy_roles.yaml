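samples:
  bait_r1:
    role: bait
    replicate: 1
  ctrl_r1:
    role: control
    replicate: 1
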