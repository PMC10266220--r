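IFNB_TREATMENT_DMP_GENES	genes with differentially methylated positions under interferon-beta treatment (combined-cohort scan)	IFI44L	IFI44	ADAR	RABGAP1L	CMPK2	RSAD2	IFIH1	SP100	PARP9	PARP14	PLSCR1	TNK2	DDX60	TAP1	TNRC18	PDE7A	LY6E	TRIM14	IFIT3	IFIT1	IFITM1	IRF7	TRIM22	PARP11	OAS1	OAS2	OASL	EPSTI1	IRF9	IFI27	B2M	BISPR	PRIC285	MX1	USP18	ODF3B
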