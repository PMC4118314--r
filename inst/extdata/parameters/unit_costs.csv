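fracture_type,cost_category,value,provenance
hip,hospital,8554,table2
other_femur,hospital,8395,table2
clinical_vertebral,hospital,6324,table2
humerus,hospital,5764,table2
pelvis,hospital,5005,table2
wrist,hospital,3794,table2
hip,rehabilitation,2187,table2
other_femur,rehabilitation,2187,table2
clinical_vertebral,rehabilitation,2092,table2
humerus,rehabilitation,2337,table2
pelvis,rehabilitation,2177,table2
wrist,rehabilitation,2337,table2
hip,outpatient_only,NA,table2
other_femur,outpatient_only,NA,table2
clinical_vertebral,outpatient_only,1614,table2
humerus,outpatient_only,835,table2
pelvis,outpatient_only,963,table2
wrist,outpatient_only,835,table2
hip,home_care,2174,table2
other_femur,home_care,2174,table2
clinical_vertebral,home_care,2212,table2
humerus,home_care,937,table2
pelvis,home_care,2174,table2
wrist,home_care,525,table2
hip,informal_care,2361,table2
other_femur,informal_care,2361,table2
clinical_vertebral,informal_care,2016,table2
humerus,informal_care,2961,table2
pelvis,informal_care,2361,table2
wrist,informal_care,581,table2
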