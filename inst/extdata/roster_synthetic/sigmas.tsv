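# synthetic reconstruction of the 86-sigma library roster
id	subgroup	organism	domain2_class	domain4_class	active	anti_screened
ECF01_7651	1	synthetic placeholder	c10_01	c35_01	TRUE	TRUE
ECF01_8711	1	synthetic placeholder	c10_01	c35_01	TRUE	TRUE
ECF02_2817	2	synthetic placeholder	c10_02	c35_02	TRUE	TRUE
ECF02_7117	2	synthetic placeholder	c10_02	c35_02	TRUE	TRUE
ECF03_5771	3	synthetic placeholder	c10_03	c35_03	TRUE	TRUE
ECF03_6265	3	synthetic placeholder	c10_03	c35_03	TRUE	TRUE
ECF04_8488	4	synthetic placeholder	c10_04	c35_04	TRUE	TRUE
ECF04_9401	4	synthetic placeholder	c10_04	c35_04	TRUE	TRUE
ECF05_1737	5	synthetic placeholder	c10_05	c35_05	FALSE	FALSE
ECF05_4869	5	synthetic placeholder	c10_05	c35_05	FALSE	FALSE
ECF06_9819	6	synthetic placeholder	c10_06	c35_06	FALSE	FALSE
ECF06_9266	6	synthetic placeholder	c10_06	c35_06	FALSE	FALSE
ECF07_7288	7	synthetic placeholder	c10_07	c35_07	FALSE	FALSE
ECF07_9447	7	synthetic placeholder	c10_07	c35_07	FALSE	FALSE
ECF08_3487	8	synthetic placeholder	c10_08	c35_08	FALSE	FALSE
ECF08_8791	8	synthetic placeholder	c10_08	c35_08	FALSE	FALSE
ECF09_2620	9	synthetic placeholder	c10_09	c35_09	FALSE	FALSE
ECF09_3822	9	synthetic placeholder	c10_09	c35_09	FALSE	FALSE
ECF10_3264	10	synthetic placeholder	c10_10	c35_10	FALSE	FALSE
ECF10_3813	10	synthetic placeholder	c10_10	c35_10	FALSE	FALSE
ECF11_987	11	synthetic placeholder	c10_01	c35_11	TRUE	TRUE
ECF11_3726	11	synthetic placeholder	c10_01	c35_11	TRUE	TRUE
ECF12_7434	12	synthetic placeholder	c10_02	c35_12	TRUE	TRUE
ECF12_9365	12	synthetic placeholder	c10_02	c35_12	TRUE	TRUE
ECF13_4177	13	synthetic placeholder	c10_03	c35_13	TRUE	TRUE
ECF13_9274	13	synthetic placeholder	c10_03	c35_13	TRUE	TRUE
ECF14_8255	14	synthetic placeholder	c10_04	c35_14	FALSE	FALSE
ECF14_2425	14	synthetic placeholder	c10_04	c35_14	FALSE	FALSE
ECF15_436	15	synthetic placeholder	c10_05	c35_15	TRUE	TRUE
ECF15_7505	15	synthetic placeholder	c10_05	c35_15	TRUE	TRUE
ECF16_3622	16	synthetic placeholder	c10_06	c35_16	TRUE	TRUE
ECF16_1321	16	synthetic placeholder	c10_06	c35_16	TRUE	TRUE
ECF17_1640	17	synthetic placeholder	c10_07	c35_01	TRUE	TRUE
ECF17_6616	17	synthetic placeholder	c10_07	c35_01	TRUE	TRUE
ECF18_2130	18	synthetic placeholder	c10_08	c35_02	TRUE	TRUE
ECF18_8634	18	synthetic placeholder	c10_08	c35_02	TRUE	TRUE
ECF19_5229	19	synthetic placeholder	c10_09	c35_03	TRUE	TRUE
ECF19_3010	19	synthetic placeholder	c10_09	c35_03	TRUE	TRUE
ECF20_992	20	synthetic placeholder	c10_10	c35_04	TRUE	TRUE
ECF20_3509	20	synthetic placeholder	c10_10	c35_04	TRUE	TRUE
ECF21_1200	21	synthetic placeholder	c10_01	c35_05	TRUE	TRUE
ECF21_4990	21	synthetic placeholder	c10_01	c35_05	TRUE	TRUE
ECF22_7414	22	synthetic placeholder	c10_02	c35_06	TRUE	TRUE
ECF22_8003	22	synthetic placeholder	c10_02	c35_06	TRUE	TRUE
ECF23_2025	23	synthetic placeholder	c10_03	c35_07	TRUE	TRUE
ECF23_6266	23	synthetic placeholder	c10_03	c35_07	TRUE	TRUE
ECF24_1652	24	synthetic placeholder	c10_04	c35_08	TRUE	TRUE
ECF24_6583	24	synthetic placeholder	c10_04	c35_08	TRUE	TRUE
ECF25_4311	25	synthetic placeholder	c10_05	c35_09	TRUE	TRUE
ECF25_6430	25	synthetic placeholder	c10_05	c35_09	TRUE	TRUE
ECF26_3917	26	synthetic placeholder	c10_06	c35_10	TRUE	FALSE
ECF26_4420	26	synthetic placeholder	c10_06	c35_10	TRUE	FALSE
ECF27_6986	27	synthetic placeholder	c10_07	c35_11	FALSE	FALSE
ECF27_5275	27	synthetic placeholder	c10_07	c35_11	FALSE	FALSE
ECF28_7692	28	synthetic placeholder	c10_08	c35_12	TRUE	FALSE
ECF28_6302	28	synthetic placeholder	c10_08	c35_12	TRUE	FALSE
ECF29_8580	29	synthetic placeholder	c10_09	c35_13	TRUE	FALSE
ECF29_5478	29	synthetic placeholder	c10_09	c35_13	TRUE	FALSE
ECF30_5012	30	synthetic placeholder	c10_10	c35_14	TRUE	FALSE
ECF30_5515	30	synthetic placeholder	c10_10	c35_14	TRUE	FALSE
ECF31_5501	31	synthetic placeholder	c10_01	c35_15	TRUE	FALSE
ECF31_3696	31	synthetic placeholder	c10_01	c35_15	TRUE	FALSE
ECF32_1882	32	synthetic placeholder	c10_02	c35_16	TRUE	FALSE
ECF32_2383	32	synthetic placeholder	c10_02	c35_16	TRUE	FALSE
ECF33_7686	33	synthetic placeholder	c10_03	c35_01	TRUE	FALSE
ECF33_8045	33	synthetic placeholder	c10_03	c35_01	TRUE	FALSE
ECF34_6750	34	synthetic placeholder	c10_04	c35_02	TRUE	FALSE
ECF34_1762	34	synthetic placeholder	c10_04	c35_02	TRUE	FALSE
ECF35_9427	35	synthetic placeholder	c10_05	c35_03	TRUE	FALSE
ECF35_4374	35	synthetic placeholder	c10_05	c35_03	TRUE	FALSE
ECF36_8016	36	synthetic placeholder	c10_06	c35_04	FALSE	FALSE
ECF36_8760	36	synthetic placeholder	c10_06	c35_04	FALSE	FALSE
ECF37_7179	37	synthetic placeholder	c10_07	c35_05	FALSE	FALSE
ECF37_1141	37	synthetic placeholder	c10_07	c35_05	FALSE	FALSE
ECF38_9722	38	synthetic placeholder	c10_08	c35_06	FALSE	FALSE
ECF38_6106	38	synthetic placeholder	c10_08	c35_06	FALSE	FALSE
ECF39_4268	39	synthetic placeholder	c10_09	c35_07	FALSE	FALSE
ECF39_6283	39	synthetic placeholder	c10_09	c35_07	FALSE	FALSE
ECF40_4540	40	synthetic placeholder	c10_10	c35_08	FALSE	FALSE
ECF40_7731	40	synthetic placeholder	c10_10	c35_08	FALSE	FALSE
ECF41_7950	41	synthetic placeholder	c10_01	c35_09	TRUE	FALSE
ECF41_8857	41	synthetic placeholder	c10_01	c35_09	TRUE	FALSE
ECF42_3887	42	synthetic placeholder	c10_02	c35_10	TRUE	FALSE
ECF42_3648	42	synthetic placeholder	c10_02	c35_10	TRUE	FALSE
ECF43_6379	43	synthetic placeholder	c10_03	c35_11	FALSE	FALSE
ECF43_9026	43	synthetic placeholder	c10_03	c35_11	FALSE	FALSE
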