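plane,phase,mean_no_pads,sd_no_pads,mean_bauer_vapor,sd_bauer_vapor,mean_bauer_nsx,sd_bauer_nsx,mean_vik_max,sd_vik_max,mean_heilong,sd_heilong,mean_ibx,sd_ibx,p_printed,f_stat,eta_sq
shoulder_flex_ext_L,si_st,41.5,24.0,38.1,26.8,35.3,21.8,38.0,22.2,35.5,25.0,41.2,19.5,0.354,1.143,0.125
shoulder_add_abd_L,si_st,23.7,7.7,23.2,7.6,22.7,5.7,19.9,5.3,23.3,7.0,20.8,60.9,0.129,1.830,0.186
shoulder_int_ext_rot_L,si_st,59.7,21.6,60.2,17.9,51.5,11.4,58.2,23.8,50.8,17.9,56.5,20.9,0.453,0.885,0.100
shoulder_flex_ext_R,si_st,23.5,8.5,22.4,10.4,21.2,5.3,21.0,8.3,18.0,6.9,23.1,8.7,0.037,2.642,0.248
shoulder_add_abd_R,si_st,25.0,6.4,23.8,6.4,25.3,6.7,23.6,9.2,22.3,5.0,21.9,5.1,0.352,1.148,0.125
shoulder_int_ext_rot_R,si_st,35.4,10.5,36.0,10.1,31.8,9.2,26.5,8.8,26.6,7.2,29.4,11.7,0.014,3.291,0.291
elbow_flex_ext_L,si_st,28.6,14.4,25.4,13.3,21.6,15.5,20.7,15.1,20.6,13.6,17.7,14.1,<0.01,4.723,0.371
forearm_pro_sup_L,si_st,18.9,8.2,14.9,6.5,14.1,6.1,16.0,5.5,12.2,3.0,16.6,6.0,0.021,3.011,0.273
elbow_flex_ext_R,si_st,34.6,15.8,30.8,14.2,34.0,18.3,34.9,19.5,33.3,16.9,34.3,17.1,0.545,0.690,0.079
forearm_pro_sup_R,si_st,20.3,9.7,18.4,7.4,20.1,6.9,21.1,11.1,20.2,10.8,19.4,5.9,0.835,0.193,0.024
shoulder_flex_ext_L,st_sr,47.3,21.4,38.43,20.6,43.7,18.8,43.7,18.9,43.1,21.5,45.0,21.7,0.151,2.174,0.214
shoulder_add_abd_L,st_sr,26.4,9.4,26.1,9.2,24.1,8.4,26.4,11.1,25.2,10.7,24.7,8.4,0.851,0.393,0.047
shoulder_int_ext_rot_L,st_sr,52.6,17.8,51,13.1,46.4,6.82,45.3,14.1,41.1,9.2,47.3,16.2,0.050,2.445,0.234
shoulder_flex_ext_R,st_sr,28.6,14.1,29.0,14.1,26.8,12.7,28.6,10.2,23.6,8.5,25.4,14.0,0.465,0.944,0.119
shoulder_add_abd_R,st_sr,29.2,8.9,23.6,5.1,24.2,3.1,23.8,5.8,21.7,5.7,23.8,5.7,0.043,2.543,0.241
shoulder_int_ext_rot_R,st_sr,51.5,21.1,48.3,21.5,49.5,21.3,39.0,21.6,46.5,16.9,39.1,20.6,0.018,3.175,0.312
elbow_flex_ext_L,st_sr,26.1,10.6,20.4,7.1,23.0,10.7,19.7,14.4,17.4,10.6,19.3,8.5,<0.01,3.576,0.309
forearm_pro_sup_L,st_sr,17.9,7.7,16.0,7.4,14.8,5.7,18.7,10.0,14.6,5.9,18.1,10.5,0.355,1.129,0.158
elbow_flex_ext_R,st_sr,43.4,13.6,37.2,18.9,43.3,22.3,41.9,20.2,42.9,22.5,40.2,18.9,0.422,0.922,0.103
forearm_pro_sup_R,st_sr,24.4,12.8,19.3,7.8,24.1,4.9,22.3,6.3,24.1,6.6,21.8,7.5,0.571,0.778,0.089
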