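fracture_type,value,provenance
hip,77,placeholder
other_femur,77,placeholder
clinical_vertebral,63,placeholder
humerus,42,placeholder
pelvis,56,placeholder
wrist,28,placeholder
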