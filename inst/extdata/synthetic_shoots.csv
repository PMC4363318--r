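"species","block","plot","diversity","shoot_height","shoot_length","internode_length","stem_mass_fraction","stem_angle_basal","stem_angle_canopy","n_secondary_axes","leaf_number","leaf_angle_max","leaf_angle_min","leaf_length","leaf_area","sla_max","sla_min","shoot_biomass"
"Lp","B1","mono_Lp_B1","monoculture","5.1948599999999999e+01","4.90334e+01","3.2085400000000002e+00","4.6465099999999998e-01","4.5624600000000001e+01","4.67836e+01","4.8943899999999996e+00","1.38591e+01","1.0870399999999999e+02","3.7871200000000002e+01","3.3305300000000003e+01","5.8346400000000003e+00","3.09405e+01","1.9041899999999998e+01","1.5007600000000001e+00"
"Lp","B2","mono_Lp_B2","monoculture","4.1968299999999999e+01","5.4942e+01","4.2504e+00","4.4976500000000003e-01","3.8686900000000001e+01","1.0331300000000001e+01","4.7406300000000003e+00","1.04754e+01","9.2722499999999997e+01","3.6746699999999997e+01","4.0606299999999997e+01","6.53695e+00","2.5216799999999999e+01","1.89495e+01","1.0678000000000001e+00"
"Lp","B1","mono_Lp_B1","monoculture","4.6974400000000003e+01","5.2274900000000002e+01","3.6200100000000002e+00","3.7831900000000002e-01","6.36738e+01","4.0944499999999998e+01","3.8877999999999999e+00","1.4251799999999999e+01","9.5637699999999995e+01","4.1304400000000001e+01","4.0055199999999999e+01","9.1949900000000007e+00","2.58032e+01","1.5911899999999999e+01","1.54874e+00"
"Lp","B1","mix_B1","mixture","4.6051499999999997e+01","6.5552400000000006e+01","4.5491000000000001e+00","4.6479300000000001e-01","5.9115400000000001e+01","3.4608899999999998e+01","5.5539199999999997e+00","1.15878e+01","1.20322e+02","4.5383699999999997e+01","3.0731100000000001e+01","3.8680400000000001e+00","2.4221e+01","2.06173e+01","1.3091299999999999e+00"
"Lp","B2","mix_B2","mixture","4.91008e+01","7.0095500000000001e+01","4.78186e+00","4.4086199999999998e-01","4.2353900000000003e+01","3.5903199999999998e+01","1.92893e+00","1.20511e+01","1.06247e+02","5.4212899999999998e+01","3.2810699999999997e+01","4.5642500000000004e+00","3.1989699999999999e+01","1.8324300000000001e+01","1.56874e+00"
"Lp","B1","mix_B1","mixture","4.1872599999999998e+01","4.8642499999999998e+01","2.7578200000000002e+00","5.6043299999999996e-01","3.6988799999999998e+01","3.19377e+01","2.2377600000000002e+00","1.44376e+01","1.1979900000000001e+02","2.77258e+01","3.6393799999999999e+01","6.76816e+00","3.21492e+01","1.79358e+01","1.1912799999999999e+00"
"Tp","B1","mono_Tp_B1","monoculture","3.1629799999999999e+01","3.97926e+01","2.6443699999999999e+00","4.0649600000000002e-01","4.44923e+01","1.9817e+01","1.84331e+00","9.1321600000000007e+00","9.7604699999999994e+01","5.1547800000000002e+01","2.234e+01","5.1230700000000002e+00","3.2677e+01","1.36477e+01","1.6089e+00"
"Tp","B2","mono_Tp_B2","monoculture","2.7177900000000001e+01","3.2863300000000002e+01","2.47288e+00","3.8667600000000002e-01","5.0885800000000003e+01","3.1822500000000002e+01","2.7701199999999999e+00","1.07188e+01","9.6816800000000001e+01","3.6714300000000001e+01","2.2566199999999998e+01","4.0254599999999998e+00","2.3142600000000002e+01","1.8093599999999999e+01","9.9651900000000004e-01"
"Tp","B1","mono_Tp_B1","monoculture","2.7795400000000001e+01","3.1960699999999999e+01","3.31324e+00","4.1655999999999999e-01","4.0440800000000003e+01","2.7203399999999998e+01","3.6866500000000002e+00","1.4189299999999999e+01","1.2029000000000001e+02","3.157e+01","2.1661000000000001e+01","3.7446000000000002e+00","2.8840599999999998e+01","2.09558e+01","1.24187e+00"
"Tp","B1","mix_B1","mixture","4.24666e+01","3.5185099999999998e+01","2.83935e+00","3.7977699999999998e-01","2.63507e+01","4.7603000000000002e+01","2.17761e+00","5.6937800000000003e+00","9.9476100000000002e+01","6.3935299999999998e+01","2.6350300000000001e+01","4.3004800000000003e+00","2.5992000000000001e+01","2.0944700000000001e+01","6.9867199999999996e-01"
"Tp","B2","mix_B2","mixture","2.4648099999999999e+01","3.6626600000000003e+01","3.5440700000000001e+00","4.4210700000000003e-01","3.5433900000000001e+01","5.3743899999999996e+01","4.77285e+00","2.3241499999999998e+01","9.24054e+01","4.1370199999999997e+01","2.5951699999999999e+01","3.6884999999999999e+00","2.9869e+01","1.7831900000000001e+01","1.12931e+00"
"Tp","B1","mix_B1","mixture","3.65276e+01","4.7859000000000002e+01","3.4350000000000001e+00","3.5056599999999999e-01","4.8582599999999999e+01","3.6990900000000003e+01","3.8905599999999998e+00","1.08561e+01","9.5459100000000007e+01","4.6954799999999999e+01","2.3430099999999999e+01","3.6830400000000001e+00","2.75366e+01","1.56866e+01","1.3160799999999999e+00"
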