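leaf_area_density,v_star,k,T_m2_per_m3
4.15,4,0.746,2.353
4.79,4,0.874,2.480
5.65,4,1.087,2.673
4.15,8,1.159,2.353
4.79,8,1.457,2.480
5.65,8,1.824,2.673
4.15,12,1.682,2.353
4.79,12,2.014,2.480
5.65,12,2.401,2.673
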