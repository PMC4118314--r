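age_class,fracture_type,value,provenance
65-69,hip,0.08,placeholder
70-74,hip,0.1,placeholder
75-79,hip,0.14,placeholder
80-84,hip,0.19,placeholder
85-89,hip,0.26,placeholder
90-94,hip,0.32,placeholder
95+,hip,0.38,placeholder
65-69,other_femur,0.064,placeholder
70-74,other_femur,0.08,placeholder
75-79,other_femur,0.112,placeholder
80-84,other_femur,0.152,placeholder
85-89,other_femur,0.208,placeholder
90-94,other_femur,0.256,placeholder
95+,other_femur,0.304,placeholder
65-69,clinical_vertebral,0.032,placeholder
70-74,clinical_vertebral,0.04,placeholder
75-79,clinical_vertebral,0.056,placeholder
80-84,clinical_vertebral,0.076,placeholder
85-89,clinical_vertebral,0.104,placeholder
90-94,clinical_vertebral,0.128,placeholder
95+,clinical_vertebral,0.152,placeholder
65-69,humerus,0.02,placeholder
70-74,humerus,0.025,placeholder
75-79,humerus,0.035,placeholder
80-84,humerus,0.0475,placeholder
85-89,humerus,0.065,placeholder
90-94,humerus,0.08,placeholder
95+,humerus,0.095,placeholder
65-69,pelvis,0.04,placeholder
70-74,pelvis,0.05,placeholder
75-79,pelvis,0.07,placeholder
80-84,pelvis,0.095,placeholder
85-89,pelvis,0.13,placeholder
90-94,pelvis,0.16,placeholder
95+,pelvis,0.19,placeholder
65-69,wrist,0.008,placeholder
70-74,wrist,0.01,placeholder
75-79,wrist,0.014,placeholder
80-84,wrist,0.019,placeholder
85-89,wrist,0.026,placeholder
90-94,wrist,0.032,placeholder
95+,wrist,0.038,placeholder
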