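# Combined amide/glutamate network dictionary grid.
# Glutamate is gridded in mM (amine protons, +3 ppm); the amine exchange
# rate values span the reported physiological-condition range
# (~7200-8300 1/s with prior reports near 5500).
# Resolution is concentrated on the two regressed fractions; the water and
# semisolid dimensions are coarser since those are estimated upstream.
water_t1: [1.3, 1.8, 2.3]
water_t2: [0.045, 0.075, 0.105]
f_ss: [0.04, 0.08, 0.12, 0.16, 0.2, 0.24, 0.28]
k_ssw: [20.0, 80.0]
f_amide: [0.0005, 0.002, 0.0035, 0.005, 0.0065, 0.008, 0.0095]
k_amide: [50.0, 200.0, 350.0, 500.0]
glu_mM: [2.0, 6.0, 10.0, 14.0, 18.0, 22.0, 26.0, 30.0]
k_glu: [5500.0, 7000.0, 8500.0]
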