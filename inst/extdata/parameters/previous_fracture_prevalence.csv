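age_class,value,provenance
50-54,0.1274,placeholder
55-59,0.1503,placeholder
60-64,0.1828,placeholder
65-69,0.2243,placeholder
70-74,0.2769,placeholder
75-79,0.3443,placeholder
80-84,0.4347,placeholder
85-89,0.5413,placeholder
90-94,0.643,placeholder
95+,0.7232,placeholder
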