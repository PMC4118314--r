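fracture_type,age_class,value,low,high,provenance
hip,50-54,3.68,3.128,4.232,placeholder
hip,55-59,3.45,2.933,3.967,placeholder
hip,60-64,3.22,2.737,3.703,placeholder
hip,65-69,2.99,2.542,3.438,placeholder
hip,70-74,2.76,2.346,3.174,placeholder
hip,75-79,2.55,2.168,2.932,placeholder
hip,80-84,2.35,1.998,2.702,placeholder
hip,85-89,2.15,1.827,2.472,placeholder
hip,90-94,2,1.7,2.3,placeholder
hip,95+,1.9,1.615,2.185,placeholder
other_femur,all,2.6,2,3.4,placeholder
clinical_vertebral,all,1.8,1.5,2.2,placeholder
humerus,all,1.9,1.6,2.3,placeholder
pelvis,all,1.6,1.3,2,placeholder
wrist,all,1.4,1.2,1.7,placeholder
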