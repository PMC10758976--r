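plane,phase,mean_no_pads,sd_no_pads,mean_bauer_vapor,sd_bauer_vapor,mean_bauer_nsx,sd_bauer_nsx,mean_vik_max,sd_vik_max,mean_heilong,sd_heilong,mean_ibx,sd_ibx,p_printed,f_stat,eta_sq
shoulder_flex_ext_L,si_sr,26.7,8.5,19.7,4.2,18.7,5.9,20.8,7.6,24.8,7.4,23.7,8.3,0.011,3.473,0.303
shoulder_add_abd_L,si_sr,15.6,7.0,14.8,4.8,14.4,6.7,13.2,5.1,14.4,6.0,14.1,6.5,0.847,0.398,0.047
shoulder_int_ext_rot_L,si_sr,33.9,16.4,32.2,15.2,31.8,19.1,31.1,17.7,33.7,16.4,30.3,16.2,0.484,0.910,0.102
shoulder_flex_ext_R,si_sr,38.1,11.7,28.7,8.0,26.9,9.1,27.6,6.0,30.5,8.8,29.0,8.0,0.048,2.475,0.236
shoulder_add_abd_R,si_sr,25.6,12.0,24.8,11.1,21.9,8.4,25.7,9.6,23.7,9.8,25.3,10.8,0.334,1.177,0.144
shoulder_int_ext_rot_R,si_sr,29.5,19.2,26.7,19.1,27.5,17.5,24.8,11.9,29.9,18.7,30.3,15.3,0.037,2.655,0.228
elbow_flex_ext_L,si_sr,29.4,13.3,18.3,7.1,20.6,6.2,19.6,13.2,16.8,8.1,25.1,12.1,0.020,4.500,0.360
forearm_pro_sup_L,si_sr,16.5,13.8,14.3,8.5,16.0,8.9,14.9,8.8,13.0,6.8,13.6,7.3,0.363,1.125,0.123
elbow_flex_ext_R,si_sr,14.3,4.8,13.4,4.5,12.8,2.2,12.4,3.3,14.7,3.2,14.7,4.2,0.306,1.275,0.137
forearm_pro_sup_R,si_sr,10.8,4.5,9.9,4.0,10.1,5.7,11.5,4.6,10.5,4.4,9.8,4.8,0.867,0.279,0.034
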