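stratum_level,stratum_label,kpi_id,numerator,denominator,value,n_missing
OVERALL,ALL,KPI1_BOTTLE,228,28,8.14,2
OVERALL,ALL,KPI1_EPISODE,228,10,22.80,1
OVERALL,ALL,KPI2,4,11,36.4,0
OVERALL,ALL,KPI3,3,4,75.0,0
OVERALL,ALL,KPI4A,2,5,40.0,0
OVERALL,ALL,KPI4B,3,5,60.0,0
OVERALL,ALL,POSITIVITY,6,11,54.5,0
OVERALL,ALL,BOTTLES_PER_EPISODE,30,11,2.73,0
OVERALL,ALL,EPISODES_PER_PATIENT,11,6,1.83,0
AREA,EMERGENCY,KPI1_BOTTLE,56,7,8.00,0
AREA,EMERGENCY,KPI1_EPISODE,56,2,28.00,0
AREA,EMERGENCY,KPI2,0,2,0.0,0
AREA,EMERGENCY,KPI3,0,0,,0
AREA,EMERGENCY,KPI4A,1,2,50.0,0
AREA,EMERGENCY,KPI4B,1,2,50.0,0
AREA,EMERGENCY,POSITIVITY,1,2,50.0,0
AREA,EMERGENCY,BOTTLES_PER_EPISODE,7,2,3.50,0
AREA,EMERGENCY,EPISODES_PER_PATIENT,2,1,2.00,0
AREA,ICU,KPI1_BOTTLE,80,10,8.00,0
AREA,ICU,KPI1_EPISODE,80,4,20.00,0
AREA,ICU,KPI2,2,4,50.0,0
AREA,ICU,KPI3,3,4,75.0,0
AREA,ICU,KPI4A,0,0,,0
AREA,ICU,KPI4B,0,0,,0
AREA,ICU,POSITIVITY,2,4,50.0,0
AREA,ICU,BOTTLES_PER_EPISODE,10,4,2.50,0
AREA,ICU,EPISODES_PER_PATIENT,4,2,2.00,0
AREA,MEDICAL,KPI1_BOTTLE,52,6,8.67,2
AREA,MEDICAL,KPI1_EPISODE,52,2,26.00,1
AREA,MEDICAL,KPI2,1,3,33.3,0
AREA,MEDICAL,KPI3,0,0,,0
AREA,MEDICAL,KPI4A,1,2,50.0,0
AREA,MEDICAL,KPI4B,1,2,50.0,0
AREA,MEDICAL,POSITIVITY,1,3,33.3,0
AREA,MEDICAL,BOTTLES_PER_EPISODE,8,3,2.67,0
AREA,MEDICAL,EPISODES_PER_PATIENT,3,2,1.50,0
AREA,SURGICAL,KPI1_BOTTLE,40,5,8.00,0
AREA,SURGICAL,KPI1_EPISODE,40,2,20.00,0
AREA,SURGICAL,KPI2,1,2,50.0,0
AREA,SURGICAL,KPI3,0,0,,0
AREA,SURGICAL,KPI4A,0,1,0.0,0
AREA,SURGICAL,KPI4B,1,1,100.0,0
AREA,SURGICAL,POSITIVITY,2,2,100.0,0
AREA,SURGICAL,BOTTLES_PER_EPISODE,5,2,2.50,0
AREA,SURGICAL,EPISODES_PER_PATIENT,2,1,2.00,0
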