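plane,task,mean_no_pads,sd_no_pads,mean_bauer_vapor,sd_bauer_vapor,mean_bauer_nsx,sd_bauer_nsx,mean_vik_max,sd_vik_max,mean_heilong,sd_heilong,mean_ibx,sd_ibx,p_printed,f_stat,eta_sq
shoulder_flexion,sho_flex,167.6,4.5,150.9,11.8,151.7,14.2,150.6,10.6,147.6,10.3,153.0,8.3,<0.01,7.362,0.479
shoulder_extension,sho_ext,46.2,7.4,39.1,10.5,41.8,13.0,38.1,9.9,35.7,10.6,39.5,8.7,0.013,3.345,0.295
shoulder_adduction,sho_add,45.7,12.2,41.1,8.5,41.7,11.7,36.3,11.0,38.3,15.2,36.4,12.0,0.016,3.152,0.259
shoulder_abduction,sho_abd,166.2,7.7,154.9,7.6,152.2,7.7,143.0,15.6,141.8,19.2,152.9,5.8,<0.01,6.653,0.454
shoulder_internal_rotation,sho_int_rot,70.7,5.7,65.8,7.6,63.9,9.1,56.5,7.7,57.5,7.8,59.7,9.7,<0.01,9.466,0.542
shoulder_external_rotation,sho_ext_rot,138.6,4.4,64.9,6.1,60.0,13.5,56.9,9.4,60.3,10.7,59.1,5.0,<0.01,4.378,0.354
elbow_flexion,elb_flex,77.7,9.7,100.9,19.7,111.2,18.1,115.3,12.7,105.1,23.0,105.5,18.7,<0.01,10.622,0.570
forearm_pronation,forearm_pro,77.7,9.7,65.1,14.0,66.2,12.9,64.3,13.4,65.0,13.7,62.6,9.6,0.035,3.651,0.313
forearm_supination,forearm_sup,74.6,8.6,65.1,13.2,70.1,10.2,67.2,12.7,64.3,16.2,64.8,14.1,0.017,3.175,0.284
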