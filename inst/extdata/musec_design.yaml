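# Two-stage O'Brien-Fleming efficacy design of the MUSEC trial:
# one-sided alpha 0.025, interim at half the planned information.
stages: 2
alpha: 0.025
info_fractions: [0.5, 1.0]
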