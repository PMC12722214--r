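# Semisolid MT network dictionary grid (7 T brain-range defaults).
# Water T2 range excludes CSF-like values; see mt_wide_t2_grid.yaml.
water_t1: [1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 2.4]
water_t2: [0.035, 0.048, 0.062, 0.075, 0.088, 0.102, 0.115]
f_ss: [0.02, 0.0297, 0.0393, 0.049, 0.0586, 0.0683, 0.0779, 0.0876,
       0.0972, 0.1069, 0.1166, 0.1262, 0.1359, 0.1455, 0.1552, 0.1648,
       0.1745, 0.1841, 0.1938, 0.2034, 0.2131, 0.2228, 0.2324, 0.2421,
       0.2517, 0.2614, 0.271, 0.2807, 0.2903, 0.30]
k_ssw: [5.0, 10.0, 15.0, 20.0, 25.0, 30.0, 35.0, 40.0, 45.0, 50.0, 55.0,
        60.0, 65.0, 70.0, 75.0, 80.0, 85.0, 90.0, 95.0, 100.0]
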