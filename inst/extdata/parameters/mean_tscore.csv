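age_class,value,provenance
50-54,-0.75,placeholder
55-59,-0.95,placeholder
60-64,-1.15,placeholder
65-69,-1.35,placeholder
70-74,-1.55,placeholder
75-79,-1.75,placeholder
80-84,-1.95,placeholder
85-89,-2.1,placeholder
90-94,-2.25,placeholder
95+,-2.35,placeholder
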