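system,e_pair,e_ch_to_n,change,e_rot90,rho_nh_o,rho_nh_n,rho_ch_o
WC-2ADW,13.06,10.51,-2.55,0.64,0.0308,0.0375,0.0047
Hoogsteen-2ADW,13.79,10.46,-3.33,1.45,0.0242,0.0350,0.0045
WC-5UZF,12.96,10.72,-2.24,-0.10,0.0281,0.0412,0.0036
Hoogsteen-5UZI,13.54,9.71,-3.83,0.28,0.0246,0.0427,0.0042
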