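# Fracture fluid chemistry, six borehole sites, April 2018 sampling.
# Analytes as rows, sites as columns; concentrations in mg/liter unless noted.
Parameter	D1	D2	D3	D4	D5	D6
Depth_m	244	244	610	1250	1478	1478
Temp_C	10.5	12	16.1	22.2	31.6	20.1
pH	7.3	7.7	7.1	8.3	8.6	8.2
ORP_mV	-68	-100	-61	-200	-149	-198
DOC	0.468	0.393	0.25	0.244	0.316	0.286
NO3-	0.3	0.3	0.3	1.1	0.7	0.3
NH4+	0.06	0.03	0.21	1.36	0.48	0
Fe2+	2.32	0.31	2.86	0	0	1.47
Total_Fe	6.08	0.35	3.30	0.03	0.00	2.44
S2-	0.006	0	0.005	0.582	0.254	0.013
DO	0.025	0.054	0.029	0.031	0.015	0
SO4-2	393	84.8	1800	315	186	4110
Cl-	15.8	18.5	17	23.7	21.3	213
CH4	7.75E-06	5.85E-06	6.88E-05	7.19E-04	3.46E-04	5.04E-03
H2	1.19E-07	1.42E-07	2.68E-07	2.16E-07	1.98E-07	3.05E-07
CO2	0.023	0.018	0.092	0.013	0.005	0.002
CO	5.56E-06	4.94E-06	8.19E-06	3.54E-06	4.14E-06	2.52E-06
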