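id	chrom	pos_bp	ref	alt
snp0001	1	260000	A	C
snp0002	1	520000	A	C
snp0003	1	780000	A	C
snp0004	1	1040000	A	C
snp0005	1	1300000	A	C
snp0006	1	1560000	A	C
snp0007	1	1820000	A	C
snp0008	1	2080000	A	C
snp0009	1	2340000	A	C
snp0010	1	2600000	A	C
snp0011	1	2860000	A	C
snp0012	1	3120000	A	C
snp0013	1	3380000	A	C
snp0014	1	3640000	A	C
snp0015	1	3900000	A	C
snp0016	1	4160000	A	C
snp0017	1	4420000	A	C
snp0018	1	4680000	A	C
snp0019	1	4940000	A	C
snp0020	1	5200000	A	C
snp0021	1	5460000	A	C
snp0022	1	5720000	A	C
snp0023	1	5980000	A	C
snp0024	1	6240000	A	C
snp0025	1	6500000	A	C
snp0026	1	6760000	A	C
snp0027	1	7020000	A	C
snp0028	1	7280000	A	C
snp0029	1	7540000	A	C
snp0030	1	7800000	A	C
snp0031	1	8060000	A	C
snp0032	1	8320000	A	C
snp0033	1	8580000	A	C
snp0034	1	8840000	A	C
snp0035	1	9100000	A	C
snp0036	1	9360000	A	C
snp0037	1	9620000	A	C
snp0038	1	9880000	A	C
snp0039	1	10140000	A	C
snp0040	1	10400000	A	C
snp0041	1	10660000	A	C
snp0042	1	10920000	A	C
snp0043	1	11180000	A	C
snp0044	1	11440000	A	C
snp0045	1	11700000	A	C
snp0046	1	11960000	A	C
snp0047	1	12220000	A	C
snp0048	1	12480000	A	C
snp0049	1	12740000	A	C
snp0050	1	13000000	A	C
snp0051	1	13260000	A	C
snp0052	1	13520000	A	C
snp0053	1	13780000	A	C
snp0054	1	14040000	A	C
snp0055	1	14300000	A	C
snp0056	1	14560000	A	C
snp0057	1	14820000	A	C
snp0058	1	15080000	A	C
snp0059	1	15340000	A	C
snp0060	1	15600000	A	C
snp0061	2	260000	A	C
snp0062	2	520000	A	C
snp0063	2	780000	A	C
snp0064	2	1040000	A	C
snp0065	2	1300000	A	C
snp0066	2	1560000	A	C
snp0067	2	1820000	A	C
snp0068	2	2080000	A	C
snp0069	2	2340000	A	C
snp0070	2	2600000	A	C
snp0071	2	2860000	A	C
snp0072	2	3120000	A	C
snp0073	2	3380000	A	C
snp0074	2	3640000	A	C
snp0075	2	3900000	A	C
snp0076	2	4160000	A	C
snp0077	2	4420000	A	C
snp0078	2	4680000	A	C
snp0079	2	4940000	A	C
snp0080	2	5200000	A	C
snp0081	2	5460000	A	C
snp0082	2	5720000	A	C
snp0083	2	5980000	A	C
snp0084	2	6240000	A	C
snp0085	2	6500000	A	C
snp0086	2	6760000	A	C
snp0087	2	7020000	A	C
snp0088	2	7280000	A	C
snp0089	2	7540000	A	C
snp0090	2	7800000	A	C
snp0091	2	8060000	A	C
snp0092	2	8320000	A	C
snp0093	2	8580000	A	C
snp0094	2	8840000	A	C
snp0095	2	9100000	A	C
snp0096	2	9360000	A	C
snp0097	2	9620000	A	C
snp0098	2	9880000	A	C
snp0099	2	10140000	A	C
snp0100	2	10400000	A	C
snp0101	2	10660000	A	C
snp0102	2	10920000	A	C
snp0103	2	11180000	A	C
snp0104	2	11440000	A	C
snp0105	2	11700000	A	C
snp0106	2	11960000	A	C
snp0107	2	12220000	A	C
snp0108	2	12480000	A	C
snp0109	2	12740000	A	C
snp0110	2	13000000	A	C
snp0111	2	13260000	A	C
snp0112	2	13520000	A	C
snp0113	2	13780000	A	C
snp0114	2	14040000	A	C
snp0115	2	14300000	A	C
snp0116	2	14560000	A	C
snp0117	2	14820000	A	C
snp0118	2	15080000	A	C
snp0119	2	15340000	A	C
snp0120	2	15600000	A	C
snp0121	3	260000	A	C
snp0122	3	520000	A	C
snp0123	3	780000	A	C
snp0124	3	1040000	A	C
snp0125	3	1300000	A	C
snp0126	3	1560000	A	C
snp0127	3	1820000	A	C
snp0128	3	2080000	A	C
snp0129	3	2340000	A	C
snp0130	3	2600000	A	C
snp0131	3	2860000	A	C
snp0132	3	3120000	A	C
snp0133	3	3380000	A	C
snp0134	3	3640000	A	C
snp0135	3	3900000	A	C
snp0136	3	4160000	A	C
snp0137	3	4420000	A	C
snp0138	3	4680000	A	C
snp0139	3	4940000	A	C
snp0140	3	5200000	A	C
snp0141	3	5460000	A	C
snp0142	3	5720000	A	C
snp0143	3	5980000	A	C
snp0144	3	6240000	A	C
snp0145	3	6500000	A	C
snp0146	3	6760000	A	C
snp0147	3	7020000	A	C
snp0148	3	7280000	A	C
snp0149	3	7540000	A	C
snp0150	3	7800000	A	C
snp0151	3	8060000	A	C
snp0152	3	8320000	A	C
snp0153	3	8580000	A	C
snp0154	3	8840000	A	C
snp0155	3	9100000	A	C
snp0156	3	9360000	A	C
snp0157	3	9620000	A	C
snp0158	3	9880000	A	C
snp0159	3	10140000	A	C
snp0160	3	10400000	A	C
snp0161	3	10660000	A	C
snp0162	3	10920000	A	C
snp0163	3	11180000	A	C
snp0164	3	11440000	A	C
snp0165	3	11700000	A	C
snp0166	3	11960000	A	C
snp0167	3	12220000	A	C
snp0168	3	12480000	A	C
snp0169	3	12740000	A	C
snp0170	3	13000000	A	C
snp0171	3	13260000	A	C
snp0172	3	13520000	A	C
snp0173	3	13780000	A	C
snp0174	3	14040000	A	C
snp0175	3	14300000	A	C
snp0176	3	14560000	A	C
snp0177	3	14820000	A	C
snp0178	3	15080000	A	C
snp0179	3	15340000	A	C
snp0180	3	15600000	A	C
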