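patient_id,age_years,center,area,hospital_service,sample_id,bottle_id,specimen_origin,bottle_type,collected_at,status,organisms,volume_ml
P1,64,C1,MEDICAL,MED-A,S01,b01,PV,AEROBIC,2023-01-05T08:00:00,POSITIVE,Staphylococcus epidermidis,10
P1,64,C1,MEDICAL,MED-A,S01,b02,PV,ANAEROBIC,2023-01-05T08:05:00,NEGATIVE,,10
P1,64,C1,MEDICAL,MED-A,S02,b03,PV,AEROBIC,2023-01-05T08:30:00,NEGATIVE,,8
P1,64,C1,MEDICAL,MED-A,S02,b04,PV,ANAEROBIC,2023-01-05T08:35:00,NEGATIVE,,8
P1,64,C1,MEDICAL,MED-A,S03,b05,PV,AEROBIC,2023-01-10T09:00:00,NEGATIVE,,
P2,71,C1,ICU,ICU-A,S04,b06,CVC,AEROBIC,2023-02-01T10:00:00,POSITIVE,Staphylococcus aureus,8
P2,71,C1,ICU,ICU-A,S04,b07,CVC,ANAEROBIC,2023-02-01T10:02:00,NEGATIVE,,8
P2,71,C1,ICU,ICU-A,S05,b08,PV,AEROBIC,2023-02-01T10:15:00,NEGATIVE,,8
P2,71,C1,ICU,ICU-A,S05,b09,PV,ANAEROBIC,2023-02-01T10:18:00,NEGATIVE,,8
P2,71,C1,ICU,ICU-A,S06,b10,CVC,AEROBIC,2023-02-20T14:00:00,NEGATIVE,,8
P2,71,C1,ICU,ICU-A,S06,b11,CVC,ANAEROBIC,2023-02-20T14:03:00,NEGATIVE,,8
P3,45,C1,SURGICAL,SURG-A,S07,b12,PV,AEROBIC,2023-03-10T07:00:00,POSITIVE,Staphylococcus hominis,8
P3,45,C1,SURGICAL,SURG-A,S07,b13,PV,ANAEROBIC,2023-03-10T07:04:00,POSITIVE,Staphylococcus hominis,8
P3,45,C1,SURGICAL,SURG-A,S08,b14,PV,AEROBIC,2023-03-10T07:30:00,NEGATIVE,,8
P3,45,C1,SURGICAL,SURG-A,S08,b15,PV,ANAEROBIC,2023-03-10T07:33:00,NEGATIVE,,8
P3,45,C1,SURGICAL,SURG-A,S09,b16,PV,AEROBIC,2023-03-12T08:00:00,POSITIVE,Escherichia coli,8
P4,38,C1,EMERGENCY,ER-A,S10,b17,PV,AEROBIC,2023-04-02T22:00:00,NEGATIVE,,8
P4,38,C1,EMERGENCY,ER-A,S10,b18,PV,ANAEROBIC,2023-04-02T22:05:00,NEGATIVE,,8
P4,38,C1,EMERGENCY,ER-A,S11,b19,PV,AEROBIC,2023-04-02T22:40:00,NEGATIVE,,8
P4,38,C1,EMERGENCY,ER-A,S12,b20,PV,AEROBIC,2023-04-05T11:00:00,POSITIVE,Klebsiella pneumoniae,8
P4,38,C1,EMERGENCY,ER-A,S12,b21,PV,ANAEROBIC,2023-04-05T11:05:00,NEGATIVE,,8
P4,38,C1,EMERGENCY,ER-A,S13,b22,PV,AEROBIC,2023-04-05T11:20:00,POSITIVE,Micrococcus luteus,8
P4,38,C1,EMERGENCY,ER-A,S13,b23,PV,ANAEROBIC,2023-04-05T11:25:00,NEGATIVE,,8
P5,59,C1,MEDICAL,MED-B,S14,b24,PV,AEROBIC,2023-05-01T10:00:00,NEGATIVE,,8
P5,59,C1,MEDICAL,MED-B,S14,b25,PV,ANAEROBIC,2023-05-01T10:05:00,NEGATIVE,,8
P5,59,C1,MEDICAL,MED-B,S15,b26,PV,AEROBIC,2023-05-02T10:00:00,NEGATIVE,,
P6,82,C1,ICU,ICU-B,S16,b27,CVC,AEROBIC,2023-06-15T06:00:00,POSITIVE,Candida albicans,8
P6,82,C1,ICU,ICU-B,S16,b28,CVC,ANAEROBIC,2023-06-15T06:05:00,NEGATIVE,,8
P6,82,C1,ICU,ICU-B,S17,b29,CVC,AEROBIC,2023-06-15T08:00:00,NEGATIVE,,8
P6,82,C1,ICU,ICU-B,S18,b30,CVC,AEROBIC,2023-06-28T09:00:00,NEGATIVE,,8
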