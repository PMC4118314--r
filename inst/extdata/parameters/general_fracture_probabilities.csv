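age_class,fracture_type,value,provenance
50-54,hip,0.00038,table1
50-54,other_femur,1e-04,table1
50-54,clinical_vertebral,0.00095,table1
50-54,humerus,0.00085,table1
50-54,pelvis,0.00018,table1
50-54,wrist,0.00221,table1
55-59,hip,0.00071,table1
55-59,other_femur,0.00014,table1
55-59,clinical_vertebral,0.00144,table1
55-59,humerus,0.00143,table1
55-59,pelvis,0.00028,table1
55-59,wrist,0.0039,table1
60-64,hip,0.00104,table1
60-64,other_femur,0.00021,table1
60-64,clinical_vertebral,0.00192,table1
60-64,humerus,0.00194,table1
60-64,pelvis,0.00038,table1
60-64,wrist,0.00491,table1
65-69,hip,0.00187,table1
65-69,other_femur,0.00033,table1
65-69,clinical_vertebral,0.00316,table1
65-69,humerus,0.00272,table1
65-69,pelvis,0.00071,table1
65-69,wrist,0.0062,table1
70-74,hip,0.00334,table1
70-74,other_femur,0.00054,table1
70-74,clinical_vertebral,0.00456,table1
70-74,humerus,0.0036,table1
70-74,pelvis,0.00127,table1
70-74,wrist,0.00684,table1
75-79,hip,0.00772,table1
75-79,other_femur,0.00102,table1
75-79,clinical_vertebral,0.00634,table1
75-79,humerus,0.0053,table1
75-79,pelvis,0.00285,table1
75-79,wrist,0.00866,table1
80-84,hip,0.01605,table1
80-84,other_femur,0.00162,table1
80-84,clinical_vertebral,0.01132,table1
80-84,humerus,0.00716,table1
80-84,pelvis,0.00544,table1
80-84,wrist,0.00973,table1
85-89,hip,0.02791,table1
85-89,other_femur,0.00262,table1
85-89,clinical_vertebral,0.01378,table1
85-89,humerus,0.00872,table1
85-89,pelvis,0.0089,table1
85-89,wrist,0.00916,table1
90-94,hip,0.03625,table1
90-94,other_femur,0.00324,table1
90-94,clinical_vertebral,0.01339,table1
90-94,humerus,0.00861,table1
90-94,pelvis,0.01172,table1
90-94,wrist,0.0074,table1
95+,hip,0.0396,table1
95+,other_femur,0.00382,table1
95+,clinical_vertebral,0.01052,table1
95+,humerus,0.00795,table1
95+,pelvis,0.01118,table1
95+,wrist,0.0053,table1
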