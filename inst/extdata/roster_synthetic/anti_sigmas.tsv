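# synthetic reconstruction of the 62 anti-sigma roster
id	cognate_sigma_id	active
AS01_7651	ECF01_7651	TRUE
AS01_8711	ECF01_8711	TRUE
AS02_2817	ECF02_2817	TRUE
AS02_7117	ECF02_7117	TRUE
AS03_5771	ECF03_5771	TRUE
AS03_6265	ECF03_6265	TRUE
AS04_8488	ECF04_8488	TRUE
AS04_9401	ECF04_9401	TRUE
AS05_1737	ECF05_1737	FALSE
AS05_4869	ECF05_4869	FALSE
AS06_9819	ECF06_9819	FALSE
AS06_9266	ECF06_9266	FALSE
AS07_7288	ECF07_7288	FALSE
AS07_9447	ECF07_9447	FALSE
AS08_3487	ECF08_3487	FALSE
AS08_8791	ECF08_8791	FALSE
AS09_2620	ECF09_2620	FALSE
AS09_3822	ECF09_3822	FALSE
AS10_3264	ECF10_3264	FALSE
AS10_3813	ECF10_3813	FALSE
AS11_987	ECF11_987	TRUE
AS11_3726	ECF11_3726	TRUE
AS12_7434	ECF12_7434	TRUE
AS12_9365	ECF12_9365	TRUE
AS13_4177	ECF13_4177	TRUE
AS13_9274	ECF13_9274	TRUE
AS14_8255	ECF14_8255	FALSE
AS14_2425	ECF14_2425	FALSE
AS15_436	ECF15_436	TRUE
AS15_7505	ECF15_7505	TRUE
AS16_3622	ECF16_3622	TRUE
AS16_1321	ECF16_1321	TRUE
AS17_1640	ECF17_1640	TRUE
AS17_6616	ECF17_6616	TRUE
AS18_2130	ECF18_2130	TRUE
AS18_8634	ECF18_8634	TRUE
AS19_5229	ECF19_5229	TRUE
AS19_3010	ECF19_3010	TRUE
AS20_992	ECF20_992	TRUE
AS20_3509	ECF20_3509	FALSE
AS21_1200	ECF21_1200	FALSE
AS21_4990	ECF21_4990	FALSE
AS22_7414	ECF22_7414	FALSE
AS22_8003	ECF22_8003	FALSE
AS23_2025	ECF23_2025	FALSE
AS23_6266	ECF23_6266	FALSE
AS24_1652	ECF24_1652	FALSE
AS24_6583	ECF24_6583	FALSE
AS25_4311	ECF25_4311	FALSE
AS25_6430	ECF25_6430	FALSE
AS26_3917	ECF26_3917	FALSE
AS26_4420	ECF26_4420	FALSE
AS27_6986	ECF27_6986	FALSE
AS27_5275	ECF27_5275	FALSE
AS28_7692	ECF28_7692	FALSE
AS28_6302	ECF28_6302	FALSE
AS29_8580	ECF29_8580	FALSE
AS29_5478	ECF29_5478	FALSE
AS30_5012	ECF30_5012	FALSE
AS30_5515	ECF30_5515	FALSE
AS31_5501	ECF31_5501	FALSE
AS31_3696	ECF31_3696	FALSE
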