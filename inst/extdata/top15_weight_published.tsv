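gene	gene_id	location_id	hil_class	closest_tss_position	coefficient	p_value	p_adjusted
CKAP2L	150468	chr2:113521873	HC	113522253	0.159	8.46e-06	0.0885
DCHS1	8642	chr11:6676514	HC	6677073	-0.221	3.92e-05	0.205
ZNF35	7584	chr3_IC:44689963-44690779	IC	44690232	-0.14	7.16e-05	0.222
HAP1	9001	chr17:39890959	HC	39890897	-0.159	8.47e-05	0.222
PIN1	5300	chr19:9945603	HC	9945882	0.152	0.000108	0.226
SERF2	10169	HCshore:44083868-44085029; ICshore:44084026-44085439	HC	44084574	0.128	0.00015	0.26
CERCAM	51148	chr9_HCshore:131182042-131183333; chr9_ICshore:131181735-131183621	HC	131182465	-0.157	0.000189	0.26
TEX10	54881	chr9:103115131	HC	103115258	-0.19	0.000199	0.26
CORO7-PAM16	100529144	chr16:4466649	HC	4466961	-0.137	0.000255	0.272
NME1-NME2	654364	chr17_HCshore:49230603-49231546; chr17_ICshore:49230561-49231528	HC	49230896	-0.109	0.00026	0.272
ARHGDIB	397	chr12:15114393	IC	15114561	-0.191	0.000314	0.298
KLK10	5655	chr19_HCshore:51520036-51521297; chr19_ICshore:51519915-51521326	HC	51522953	-0.142	0.000439	0.383
ZNF215	7762	chr11:6947572	HC	6947653	-0.164	0.000729	0.549
HEATR6	63897	chr17:58156231	HC	58156291	0.132	0.000754	0.549
SLC22A18	5002	chr11_IC:2923161-2923957	IC	2923511	-0.134	0.000965	0.549
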