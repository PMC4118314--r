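parameter,value,provenance
ltc_yearly_cost,25759,table2
discount_rate,0.03,paper_text
base_year,2009,paper_text
wage_growth,0.02,paper_text
retirement_age,65,placeholder
nh_min_entry_age,65,paper_text
friction_period_years,0.25,placeholder
work_days_per_year,250,placeholder
yearly_earnings,36000,placeholder
informal_opportunity_factor,1.45,placeholder
informal_minimum_factor,0.65,placeholder
bmd_threshold,-2.5,paper_text
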