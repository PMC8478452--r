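# Standard-state thermodynamic properties at 298.15 K, 1 bar.
# Values transcribed from standard compilations (SUPCRT92-consistent aqueous
# species after Shock & Helgeson; minerals after Robie & Hemingway; NBS tables
# for acetate and perchlorate). Each record carries its source. The ferrihydrite
# record is a conventional amorphous-FeOOH value chosen to sit above (less
# stable than) lepidocrocite and goethite; see the package vignette.
# Columns: name formula phase charge dG_f_kJ_mol dH_f_kJ_mol ion_size_A source
name	formula	phase	charge	dG_f_kJ_mol	dH_f_kJ_mol	ion_size_A	source
H2O	H2O	liquid-water	0	-237.18	-285.83	NA	SUPCRT92 (Johnson et al. 1992)
H+	H	aqueous	1	0	0	9.0	convention
OH-	HO	aqueous	-1	-157.30	-230.02	3.5	SUPCRT92 (Johnson et al. 1992)
O2(aq)	O2	aqueous	0	16.54	-12.24	NA	Shock et al. 1989
H2(aq)	H2	aqueous	0	17.72	-4.04	NA	Shock et al. 1989
Fe+2	Fe	aqueous	2	-91.50	-92.26	6.0	Shock & Helgeson 1988
NO3-	NO3	aqueous	-1	-110.91	-206.85	3.0	Shock & Helgeson 1988
NO2-	NO2	aqueous	-1	-32.22	-104.60	3.0	Shock & Helgeson 1988
NH4+	NH4	aqueous	1	-79.45	-133.26	2.5	Shock & Helgeson 1988
HCO3-	HCO3	aqueous	-1	-586.94	-689.93	4.0	Shock & Helgeson 1988
CO3-2	CO3	aqueous	-2	-527.98	-675.23	4.5	Shock & Helgeson 1988
CO2(aq)	CO2	aqueous	0	-386.00	-413.84	NA	Shock & Helgeson 1988
CO(aq)	CO	aqueous	0	-120.00	-120.96	NA	Shock et al. 1989
CH4(aq)	CH4	aqueous	0	-34.35	-87.81	NA	Shock & Helgeson 1990
acetate	C2H3O2	aqueous	-1	-369.31	-486.01	4.5	NBS (Wagman et al. 1982)
SO4-2	SO4	aqueous	-2	-744.53	-909.27	4.0	Shock & Helgeson 1988
HS-	HS	aqueous	-1	11.97	-16.22	3.5	Shock & Helgeson 1988
S0	S	mineral	0	0	0	NA	element, convention
Cl-	Cl	aqueous	-1	-131.29	-167.08	3.0	Shock & Helgeson 1988
ClO4-	ClO4	aqueous	-1	-8.52	-129.33	3.5	NBS (Wagman et al. 1982)
Na+	Na	aqueous	1	-261.88	-240.30	4.0	Shock & Helgeson 1988
K+	K	aqueous	1	-282.46	-252.14	3.0	Shock & Helgeson 1988
Ca+2	Ca	aqueous	2	-552.79	-543.07	6.0	Shock & Helgeson 1988
ferrihydrite	FeOOH	mineral	0	-474.30	-544.00	NA	synthetic 2-line ferrihydrite on FeOOH basis (cf. Majzlan et al. 2004)
goethite	FeOOH	mineral	0	-488.55	-559.33	NA	Robie & Hemingway 1995
lepidocrocite	FeOOH	mineral	0	-480.14	-549.40	NA	Majzlan et al. 2003
hematite	Fe2O3	mineral	0	-742.24	-824.25	NA	Robie & Hemingway 1995
magnetite	Fe3O4	mineral	0	-1012.57	-1115.73	NA	Robie & Hemingway 1995
pyrite	FeS2	mineral	0	-160.06	-171.54	NA	Robie & Hemingway 1995
siderite	FeCO3	mineral	0	-681.60	-753.00	NA	consistent with log Ksp -10.89 (PHREEQC) and Fe+2, CO3-2 above
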