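species,delta
water,43.5
ethanol,24.6
resveratrol,26.4
A,28.7
B,16.2
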