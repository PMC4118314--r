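age_class,value,provenance
65-69,0.01,placeholder
70-74,0.018,placeholder
75-79,0.035,placeholder
80-84,0.075,placeholder
85-89,0.155,placeholder
90-94,0.28,placeholder
95+,0.42,placeholder
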