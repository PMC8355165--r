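organism	label	filtered_irs	identified	derived	ahead	part_match	full_match	percent_printed
Staphylococcus aureus Newman	A	870	719	671	210	72	389	69
Clostridium phytofermentans	B	1259	1076	991	530	107	354	47
Mycobacterium gilvum	C	1308	1187	1135	263	357	515	77
Bifidobacterium pseudocatenulatum	D	468	399	364	120	69	175	67
Treponema denticola	E	612	503	455	112	95	248	75
Leptospira interrogans	F	1338	1162	1090	285	220	585	74
Fusobacterium nucleatum	G	455	335	293	98	40	155	67
Nostoc punctiforme	H	2464	2124	1996	545	398	1053	73
Prochlorococcus marinus	I	803	685	646	108	172	366	83
Nodularia spumigena	J	1843	1621	1491	397	277	817	73
Pseudomonas aeruginosa	K	1585	1439	1378	329	409	640	76
Syntrophus aciditrophicus	L	955	816	773	161	221	391	79
Klebsiella pneumoniae	M	778	721	631	207	132	292	67
Sigma	ALL	14738	12787	11914	3365	2569	5980	72
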