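age_class,value,provenance
50-54,0.76,placeholder
55-59,0.65,placeholder
60-64,0.21,placeholder
65-69,0,placeholder
70-74,0,placeholder
75-79,0,placeholder
80-84,0,placeholder
85-89,0,placeholder
90-94,0,placeholder
95+,0,placeholder
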