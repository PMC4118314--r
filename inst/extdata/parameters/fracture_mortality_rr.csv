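fracture_type,bucket,value,provenance
hip,1,3,placeholder
hip,2-5,1.9,placeholder
hip,6-10,1.5,placeholder
other_femur,1,3,placeholder
other_femur,2-5,1.9,placeholder
other_femur,6-10,1.5,placeholder
clinical_vertebral,1,2.6,placeholder
clinical_vertebral,2-5,1.7,placeholder
clinical_vertebral,6-10,1.4,placeholder
humerus,1,1.9,placeholder
humerus,2-5,1.4,placeholder
humerus,6-10,1.2,placeholder
pelvis,1,2.2,placeholder
pelvis,2-5,1.5,placeholder
pelvis,6-10,1.3,placeholder
wrist,1,1,paper_text
wrist,2-5,1,paper_text
wrist,6-10,1,paper_text
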