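ingredient	atc_class	n_reports	phenotype	ic025	ror	bs
esomeprazole	A	9198	renal injury	6.8	184.23	4
pantoprazole	A	3403	tubulointerstitial nephritis	6.3	109.86	4
tenofovir disoproxil	J	6461	renal failure	6.0	90.72	4
efavirenz + emtricitabine + tenofovir disoproxil	J	4359	renal failure	5.9	76.08	4
colistin	J	956	blood creatinine increased	5.7	66.70	4
furosemide	C	5935	acute kidney injury	3.9	17.72	4
tacrolimus	L	2115	blood creatinine increased	3.6	13.12	4
omeprazole	A	456	tubulointerstitial nephritis	6.0	6.91	4
ibuprofen	M	625	tubulointerstitial nephritis	2.6	6.76	4
emtricitabine + tenofovir disoproxil	J	7781	renal injury	7.9	432.36	3
sodium phosphate	A	728	acute kidney injury	5.4	57.80	3
basiliximab	L	85	tubulointerstitial nephritis	4.7	41.53	3
spironolactone	C	2644	acute kidney injury	4.3	22.28	3
vancomycin	J	3395	blood creatinine increased	5.8	20.73	3
canagliflozin	A	1801	acute kidney injury	4.0	18.48	3
acyclovir	J	2097	acute kidney injury	3.6	13.68	3
lenalidomide	L	3507	renal failure	1.7	3.50	3
methotrexate	L	2654	acute kidney injury	1.5	2.93	3
inotersen	N	182	glomerular filtration rate decreased	7.7	604.57	2
ciclosporine	L	1495	blood creatinine increased	3.4	11.86	2
rivaroxaban	L	3425	acute kidney injury	2.1	4.64	2
cobicistat + elvitegravir + emtricitabine + tenofovir disoproxil	J	3105	renal injury	8.7	786.96	1
metformine	A	5232	acute kidney injury	3.5	9.92	0
covid-19 vaccine	J	5407	acute kidney injury	-2.0	0.24	0
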