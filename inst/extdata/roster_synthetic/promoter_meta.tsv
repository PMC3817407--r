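# synthetic reconstruction of the 29-promoter roster
id	cognate_subgroup	active	up_modified	source
P_01_7651	1	TRUE	FALSE	synthetic reconstruction
P_02_2817	2	TRUE	FALSE	synthetic reconstruction
P_03_5771	3	TRUE	FALSE	synthetic reconstruction
P_04_8488	4	TRUE	FALSE	synthetic reconstruction
P_11_3726	11	TRUE	FALSE	synthetic reconstruction
P_12_7434	12	TRUE	FALSE	synthetic reconstruction
P_13_4177	13	TRUE	FALSE	synthetic reconstruction
P_14_8255	14	FALSE	FALSE	synthetic reconstruction
P_15_UP436	15	TRUE	TRUE	synthetic reconstruction
P_16_3622	16	TRUE	FALSE	synthetic reconstruction
P_17_1640	17	TRUE	FALSE	synthetic reconstruction
P_18_2130	18	TRUE	FALSE	synthetic reconstruction
P_19_5229	19	TRUE	FALSE	synthetic reconstruction
P_20_992	20	TRUE	FALSE	synthetic reconstruction
P_21_1200	21	TRUE	FALSE	synthetic reconstruction
P_22_7414	22	TRUE	FALSE	synthetic reconstruction
P_23_2025	23	TRUE	FALSE	synthetic reconstruction
P_24_1652	24	TRUE	FALSE	synthetic reconstruction
P_25_UP4311	25	TRUE	TRUE	synthetic reconstruction
P_26_3917	26	TRUE	FALSE	synthetic reconstruction
P_27_6986	27	FALSE	FALSE	synthetic reconstruction
P_28_7692	28	TRUE	FALSE	synthetic reconstruction
P_29_8580	29	TRUE	FALSE	synthetic reconstruction
P_30_5012	30	TRUE	FALSE	synthetic reconstruction
P_31_5501	31	TRUE	FALSE	synthetic reconstruction
P_32_1882	32	TRUE	FALSE	synthetic reconstruction
P_33_7686	33	FALSE	FALSE	synthetic reconstruction
P_34_6750	34	TRUE	FALSE	synthetic reconstruction
P_35_9427	35	TRUE	FALSE	synthetic reconstruction
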