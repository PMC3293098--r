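id,value
gdp_per_capita,474.27
discount_rate,0.03
age_at_death,28
remaining_life_expectancy,40
annual_incidence,362000
anc_attendance,0.94
cesarean_rate,0.157
facility_delivery_rate,0.393
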