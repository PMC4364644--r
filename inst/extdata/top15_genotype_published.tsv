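gene	gene_id	location_id	hil_class	closest_tss_position	coefficient	p_value	p_adjusted
REM1	28954	chr20_IC:30062552-30063794	IC	30063104	-0.0931	5.76e-06	0.0324
TERT	7015	chr5_HCshore:1294078-1296099; chr5_ICshore:1292899-1296102	HC	1295161	-0.149	1.03e-05	0.0324
DRD5	1816	chr4:9782881	ICshore	9783257	-0.16	1.13e-05	0.0324
TRPC3	7222	chr4:122853965	HC	122854196	-0.25	1.72e-05	0.0324
FOXD1	2297	chr5:72744904	ICshore	72744351	-0.115	1.84e-05	0.0324
ESPNL	339768	chr2:239008986	IC	239008950	-0.158	1.86e-05	0.0324
ZFYVE9	9372	chr1:52608558	HC	52608045	-0.133	2.37e-05	0.0354
NPY4R	5540	chr10:47083233	IC	47083533	-0.213	3.25e-05	0.0393
PKP1	5317	chr1_HCshore:201252407-201253409; chr1_ICshore:201252275-201253817	HC	201252579	-0.175	4.21e-05	0.0393
FAM118A	55007	chr22:45705265	HC	45705080	-0.279	4.32e-05	0.0393
CEBPE	1053	chr14:23588162	IC	23588819	-0.134	4.47e-05	0.0393
CORO7	79585	chr16:4465731	ICshore	4465897	-0.144	4.5e-05	0.0393
CHST8	64377	chr19:34175481	IC	34175433	-0.145	8.08e-05	0.065
NAA40	79829	chr11:63705946	HC	63706441	0.107	9.22e-05	0.0674
CELSR1	9620	chr22_HCshore:46931364-46934654; chr22_ICshore:46929131-46935234	HC	46933066	-0.205	9.97e-05	0.0674
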