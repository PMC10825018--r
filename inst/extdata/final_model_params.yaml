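k1: 9.65
k-1': 19.600000000000001
k2': 13.5
k-2': 1.11
k3': 13.0
k-3: 0.0
phi_x: 9.0
phi_v: 0.101
phi_l: 3.89
K: 3150.0
Ks: 45.0
kd_ATP: 2.36
kd_Pi: 5.0
xC0: 0.01
Lmax: 2.3
L_rest: 1.9
phi_s-2: 995.0
phi_s3: 71.099999999999994
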