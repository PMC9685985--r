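sample,sum_gv_1064,sum_gv_b,bvtv_percent,modulus_graph,printed_infill_percent
Femur 1,1.74e8,4.41e6,15.8,150,27
Femur 2,7.52e7,2.74e6,11,60,16
Femur 3,9.85e7,3.82e6,10.3,60,16
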