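item,unit_label,unit_cost_eur,category,source
psychiatric_inpatient_day,day,386,Inpatient care,Local clinic per-diem
somatic_inpatient_day,day,576,Inpatient care,Published remuneration index
day_care_day,day,168,Psychiatric day care,Local clinic per-diem
psychiatrist_visit,visit,45,Outpatient care,Published remuneration index
gp_visit,visit,20,Outpatient care,Published remuneration index
sheltered_workplace_day,day,48,Complementary care,Administrative district
occupational_therapy_unit,unit,38,Complementary care,Published remuneration index
physical_therapy_unit,unit,16,Complementary care,Published remuneration index
day_structuring_unit,unit,33,Complementary care,Published remuneration index
contact_counseling_center_visit,visit,29,Complementary care,Local service provider
home_nursing_visit,visit,22,Complementary care,Provider-insurer cost agreement
police_contact,unit,62,Complementary care,State ordinance on administrative fees
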