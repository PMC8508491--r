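condition,mean_charge,mean_charge_sd,a1,a2,x0,dx,slope
4.5/5,7.3,0.1,63.00,0.84,21.10,6.59,-2.36
7/5,6.9,0.1,100.00,5.60,13.01,2.37,-9.94
7/10,6.4,0.2,86.00,8.77,12.50,2.30,-8.39
7/20,6.1,0.6,90.00,5.99,14.90,2.60,-8.08
7/30,6.4,0.2,86.00,9.04,13.30,2.20,-8.75
7/40,6.5,0.2,84.75,7.65,13.66,2.08,-9.28
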