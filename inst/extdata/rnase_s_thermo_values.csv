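condition,k_m0g,kd_m0g,dg_m0g,dh_m0g,tds_m0g
4.5/5,6.90e11,4.39e-12,64.79,-1.83,-66.54
7/5,1.03e10,3.71e-12,65.21,1.28,-63.83
7/10,5.00e10,3.97e-12,65.04,0.76,-64.22
7/20,2.09e10,3.83e-12,65.13,0.84,-64.20
7/30,2.80e10,3.87e-12,65.10,0.94,-64.09
7/40,1.71e10,3.79e-12,65.15,1.12,-63.95
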