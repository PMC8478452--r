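# Iron-metabolism reaction library, as printed (48 reactions after FeOOH
# expansion). Generic FeOOH electron-acceptor rows carry an id range and are
# instantiated for ferrihydrite, goethite and lepidocrocite (in that order) by
# expand_library(); unqualified FeOOH produced by Fe+2-donor rows is bound to
# ferrihydrite (fresh precipitate) at expansion. Four rows (6, 43, 44, 45) do
# not balance as printed; see reaction_library_rebalanced.tsv.
# Columns: id equation iron_species role printed_n_e
id	equation	iron_species	role	printed_n_e
1	8Fe+2 + ClO4- + 12H2O = 8FeOOH + Cl- + 16H+	Fe+2	iron-as-donor	8
2	6Fe+2 + CO + 11H2O = 6FeOOH + CH4 + 12H+	Fe+2	iron-as-donor	6
3	8Fe+2 + HCO3- + 13H2O = 8FeOOH + CH4 + 15H+	Fe+2	iron-as-donor	8
4	8Fe+2 + 2HCO3- + 12H2O = 8FeOOH + acetate + 15H+	Fe+2	iron-as-donor	8
5	8Fe+2 + NO3- + 13H2O = 8FeOOH + NH4+ + 14H+	Fe+2	iron-as-donor	8
6	8Fe+2 + NO3- + 13H2O = 8FeOOH + NO2- + 14H+	Fe+2	iron-as-donor	2
7	4Fe+2 + O2 + 6H2O = 4FeOOH + 8H+	Fe+2	iron-as-donor	4
8-10	8FeOOH + acetate + 15H+ = 8Fe+2 + 2HCO3- + 12H2O	FeOOH	iron-as-acceptor	8
11-13	8FeOOH + CH4 + 15H+ = 8Fe+2 + HCO3- + 13H2O	FeOOH	iron-as-acceptor	8
14-16	6FeOOH + CH4 + 12H+ = 6Fe+2 + CO + 11H2O	FeOOH	iron-as-acceptor	6
17-19	2FeOOH + CO + 3H+ = 2Fe+2 + HCO3- + 2H2O	FeOOH	iron-as-acceptor	2
20-22	2FeOOH + H2 + 4H+ = 2Fe+2 + 4H2O	FeOOH	iron-as-acceptor	2
23-25	2FeOOH + HS- + 5H+ = 2Fe+2 + S0 + 4H2O	FeOOH	iron-as-acceptor	2
26-28	6FeOOH + NH4+ + 10H+ = 6Fe+2 + NO2- + 10H2O	FeOOH	iron-as-acceptor	6
29	4Fe2O3 + acetate + 15H+ = 8Fe+2 + 2HCO3- + 8H2O	hematite	iron-as-acceptor	8
30	4Fe2O3 + CH4 + 15H+ = 8Fe+2 + HCO3- + 9H2O	hematite	iron-as-acceptor	8
31	3Fe2O3 + CH4 + 12H+ = 6Fe+2 + CO + 8H2O	hematite	iron-as-acceptor	6
32	Fe2O3 + CO + 3H+ = 2Fe+2 + HCO3- + H2O	hematite	iron-as-acceptor	2
33	Fe2O3 + H2 + 4H+ = 2Fe+2 + 3H2O	hematite	iron-as-acceptor	2
34	Fe2O3 + HS- + 5H+ = 2Fe+2 + S0 + 3H2O	hematite	iron-as-acceptor	2
35	3Fe2O3 + NH4+ + 10H+ = 6Fe+2 + NO2- + 7H2O	hematite	iron-as-acceptor	6
36	4Fe3O4 + acetate + 23H+ = 12Fe+2 + 2HCO3- + 12H2O	magnetite	iron-as-acceptor	8
37	4Fe3O4 + CH4 + 23H+ = 12Fe+2 + HCO3- + 13H2O	magnetite	iron-as-acceptor	8
38	3Fe3O4 + CH4 + 18H+ = 9Fe+2 + CO + 11H2O	magnetite	iron-as-acceptor	6
39	Fe3O4 + CO + 5H+ = 3Fe+2 + HCO3- + 2H2O	magnetite	iron-as-acceptor	2
40	Fe3O4 + H2 + 6H+ = 3Fe+2 + 4H2O	magnetite	iron-as-acceptor	2
41	Fe3O4 + HS- + 7H+ = 3Fe+2 + S0 + 4H2O	magnetite	iron-as-acceptor	2
42	3Fe3O4 + NH4+ + 16H+ = 9Fe+2 + NO2- + 10H2O	magnetite	iron-as-acceptor	6
43	3FeS2 + 8CO + 16H2O = 3Fe+2 + 6SO4-2 + 8CH4	pyrite	iron-as-donor	48
44	3FeS2 + 2HCO3- + 2H2O + 2H+ = Fe+2 + 2SO4-2 + 2CH4	pyrite	iron-as-donor	16
45	FeS2 + 8NO3- = Fe+2 + 2SO4-2 + 8NO2-	pyrite	iron-as-donor	16
46	6FeCO3 + CO + 11H2O = 6FeOOH_fer + 6HCO3- + CH4 + 6H+	siderite	iron-as-donor	6
47	2FeCO3 + NO3- + 3H2O = 2FeOOH_fer + NO2- + 2HCO3- + 2H+	siderite	iron-as-donor	2
48	8FeCO3 + SO4-2 + 12H2O = 8FeOOH_fer + HS- + 8HCO3- + 7H+	siderite	iron-as-donor	8
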