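fracture_type,parameter,value,provenance
hip,hospitalization_prob,1,paper_text
other_femur,hospitalization_prob,1,paper_text
clinical_vertebral,hospitalization_prob,0.45,placeholder
humerus,hospitalization_prob,0.6,placeholder
pelvis,hospitalization_prob,0.8,placeholder
wrist,hospitalization_prob,0.25,placeholder
hip,rehab_prob,0.5,placeholder
other_femur,rehab_prob,0.5,placeholder
clinical_vertebral,rehab_prob,0.3,placeholder
humerus,rehab_prob,0.2,placeholder
pelvis,rehab_prob,0.35,placeholder
wrist,rehab_prob,0.05,placeholder
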