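parameter	control	ifg	t2d	p_value
female_sex_pct	60	60	60
age_yrs	53.50 (47-58)	51.50 (47-61)	58 (57-65)	0.167
bmi_kg_m2	26 (22-28)	28 (25-30)	29 (27-30)	0.060
sbp_mmhg	120 (119-120)	120 (120-130)	120 (120-125)	0.170
dbp_mmhg	80 (78-80)	85 (80-85)	80 (80-85)	0.048
fasting_glucose_mg_dl	88 (83-91)	113 (105-118)	135 (118-165)	<0.001
hba1c_pct	5.10 (4.98-5.38)	5.70 (5.43-6.10)	6.20 (6.0-6.60)	<0.001
total_cholesterol_mg_dl	179 (160-200)	204 (178-223)	185 (165-210)	0.337
ldl_cholesterol_mg_dl	110 (93-125)	142 (109-158)	113 (103-125)	0.133
hdl_cholesterol_mg_dl	57 (44-60)	42 (37-56)	55 (40-56)	0.207
triglycerides_mg_dl	88 (75-127)	103 (67-158)	120 (93-144)	0.480
crp_mg_l	3.16 (3.16-3.36)	3.45 (3.16-10)	4.08 (0.64-5.75)	0.659
esr_mm_h	6.50 (4.75-14.25)	9.50 (3.75-28.25)	9.0 (5.0-10)	0.806
t2d_duration_yrs			2 (0-2)
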