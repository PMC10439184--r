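ref_id	family	is_ppr	tuning_site	helix_cf_start	helix_cf_end	lambda_max_nm	domain	taxon
AAG10475.1	PR	TRUE	105	62	211	525	prokaryote	uncultured gamma proteobacterium
AAK30179.1	PR	TRUE	105	62	211	490	prokaryote	uncultured marine bacterium
BAN14807.1	PR	TRUE	105	62	211	525	prokaryote	uncultured marine bacterium
AAZ21446.1	PR	TRUE	105	62	211	490	prokaryote	uncultured marine bacterium
PR_KMIC_SYN	PR	TRUE	105	62	211	490	eukaryote	Karlodinium micrum
PR_CFUS_SYN	PR	TRUE	105	62	211	490	eukaryote	Ceratium fusus
PR_AAND_SYN	PR	TRUE	105	62	211	525	eukaryote	Alexandrium andersonii
AIN36550.1	XR	TRUE		66	216		prokaryote	Nonlabens marinus
ADY17811.1	XR	TRUE		66	216		prokaryote	uncultured marine bacterium
ABV22426.1	XR	TRUE		66	216		prokaryote	uncultured marine bacterium
AAO14677.1	XR	TRUE		66	216		prokaryote	Salinibacter ruber
BAC88139.1	GR	TRUE		70	218		prokaryote	Gloeobacter violaceus
BR_HALSAL_SYN	BR	TRUE		75	225		prokaryote	Halobacterium salinarum
SRI_HALSAL_SYN	SRI	FALSE		70	215		prokaryote	Halobacterium salinarum
SRII_HALVAL_SYN	other_rhodopsin	FALSE		70	215		prokaryote	Haloarcula vallismortis
VIRR_OLV1_SYN	other_rhodopsin	FALSE		60	205		virus	Organic Lake phycodnavirus
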