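item_id,family,eta,xi,delta
RE4,rh,0.94,0.47,-0.12
RE16,rh,0.84,0.69,0.28
RE17,rh,1.02,0.77,0.44
RE19,rh,0.82,0.47,0.94
LT7,rh,0.91,0.39,0.56
LT33,rh,0.79,0.27,0.44
LT34,rh,0.94,0.50,1.05
LT58,rh,0.84,-0.18,0.20
MX45,rh,0.62,0.13,0.55
MX46,rh,0.65,0.17,0.26
MX47,rh,0.78,0.38,0.23
MX55,rh,0.52,-0.40,-0.29
MR3,rh,1.03,-1.29,-2.45
MR4,rh,1.12,-1.29,-2.64
MR6,rh,0.91,-0.84,-1.27
MR8,rh,0.94,-1.27,-1.53
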