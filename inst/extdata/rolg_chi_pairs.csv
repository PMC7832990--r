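species_i,species_j,chi,a_printed
water,resveratrol,-0.75,15.4
water,A,-3.04,12.1
water,B,5.10,23.9
water,ethanol,-0.07,16.4
resveratrol,A,-1.22,14.9
resveratrol,B,0.07,16.6
resveratrol,ethanol,0.34,17.0
A,B,1.03,18.0
A,ethanol,-0.40,16.1
B,ethanol,0.48,17.2
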