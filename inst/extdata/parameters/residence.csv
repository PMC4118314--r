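parameter,fracture_type,value,provenance
rr_mortality_nh,all,2.2,placeholder
rr_mortality_community,all,0.97,placeholder
nh_population_share,all,0.05,placeholder
rr_fracture_nh,hip,2.2,placeholder
rr_fracture_nh,other_femur,2.2,placeholder
rr_fracture_nh,clinical_vertebral,1.3,placeholder
rr_fracture_nh,humerus,1.4,placeholder
rr_fracture_nh,pelvis,1.6,placeholder
rr_fracture_nh,wrist,0.9,placeholder
rr_fracture_community,hip,0.93684,placeholder
rr_fracture_community,other_femur,0.93684,placeholder
rr_fracture_community,clinical_vertebral,0.98421,placeholder
rr_fracture_community,humerus,0.97895,placeholder
rr_fracture_community,pelvis,0.96842,placeholder
rr_fracture_community,wrist,1.00526,placeholder
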