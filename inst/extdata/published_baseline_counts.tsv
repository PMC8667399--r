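variable	level	n_all	pct_all	n_no	pct_no	n_yes	pct_yes
smoking	never	2253	43.9	1680	44.9	573	41.2
smoking	former	2699	52.6	1952	52.2	747	53.7
smoking	current	179	3.5	107	2.9	72	5.2
alcohol	never	461	9.0	359	9.6	102	7.3
alcohol	former	294	5.7	211	5.6	83	6.0
alcohol	current	4376	85.3	3169	84.8	1207	86.7
treatment	placebo	2564	50.0	1878	50.2	686	49.3
treatment	aspirin	2567	50.0	1861	49.8	706	50.7
bmi	underweight	38	0.8	23	0.6	15	1.1
bmi	normal	1063	21.0	754	20.5	309	22.5
bmi	overweight	2633	52.1	1921	52.2	712	51.9
bmi	obese	1298	25.7	969	26.3	329	24.0
bmi	missing	18	0.4	12	0.3	6	0.4
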