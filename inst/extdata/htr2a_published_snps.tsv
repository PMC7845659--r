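snp	section	position	maf_a	or_a	p_a	maf_b	or_b	p_b	mega_maf	mega_or	mega_p	meta_p
rs7333412	remitted	47403360	0.1779	1.91	6.1e-3	0.1518	2.00	5.2e-2	0.1659	1.88	9.0e-4	2.9e-3
rs7324017	remitted	47406845	0.1779	1.91	6.1e-3	0.1488	2.05	4.4e-2	0.1647	1.91	7.1e-4	2.5e-3
rs3803189	remitted	47408570	0.1779	1.91	6.1e-3	0.1467	2.10	3.9e-2	0.1639	1.93	5.9e-4	2.2e-3
rs3125	remitted	47408851	0.1779	1.91	6.1e-3	0.1467	2.10	3.9e-2	0.1639	1.93	5.9e-4	2.2e-3
rs7322347	remitted	47410103	0.2321	2.19	5.3e-4	0.2024	2.10	2.6e-2	0.2190	2.04	6.9e-4	1.7e-4
chr13:47410325:D	remitted	47410325	0.1844	1.91	6.7e-3	0.1509	2.16	3.5e-2	0.1695	1.95	5.8e-4	2.2e-3
rs1923882	remitted	47411661	0.1786	1.90	6.8e-3	0.1488	2.05	4.4e-2	0.1651	1.90	7.7e-4	2.7e-3
rs55948462	remitted	47412075	0.1786	1.90	6.8e-3	0.1467	2.10	3.9e-2	0.1643	1.92	6.4e-4	2.4e-3
rs56005991	remitted	47412741	0.1873	2.18	1.1e-3	0.1647	1.89	6.3e-2	0.1775	2.01	2.1e-4	7.4e-4
rs977003	remitted	47415001	0.2312	2.21	4.5e-4	0.2054	2.01	3.3e-2	0.2209	2.00	8.8e-5	1.8e-4
rs61948314	remitted	47415383	0.1714	1.95	5.9e-3	0.1402	2.10	4.2e-2	0.1575	1.98	4.9e-4	2.3e-3
rs75907607	remitted	47416042	0.1714	1.95	5.9e-3	0.1402	2.10	4.2e-2	0.1575	1.98	4.9e-4	2.3e-3
rs17068986	remitted	47416386	0.4822	0.51	5.2e-4	0.4940	0.73	2.8e-1	0.4883	0.59	6.0e-4	1.2e-3
rs76703096	remitted	47416712	0.1390	1.84	2.5e-2	0.1180	1.97	8.5e-2	0.1296	1.86	4.1e-3	1.5e-2
rs7333412	response	47403360	0.1779	1.72	2.0e-2	0.1518	1.86	5.6e-2	0.1659	1.72	3.7e-3	8.7e-3
rs3803189	response	47408570	0.1779	1.72	2.0e-2	0.1467	1.80	7.1e-2	0.1639	1.71	4.4e-3	1.1e-2
rs3125	response	47408851	0.1779	1.72	2.0e-2	0.1467	1.80	7.1e-2	0.1639	1.71	4.4e-3	1.1e-2
chr13:47410325:D	response	47410325	0.1844	1.69	2.6e-2	0.1509	1.97	4.3e-2	0.1695	1.74	3.6e-3	8.8e-3
rs55948462	response	47412075	0.1786	1.71	2.2e-2	0.1467	1.80	7.1e-2	0.1643	1.70	4.7e-3	1.2e-2
rs61948314	response	47415383	0.1714	1.75	1.9e-2	0.1402	1.88	5.9e-2	0.1575	1.77	3.1e-3	8.9e-3
rs75907607	response	47416042	0.1714	1.75	1.9e-2	0.1402	1.88	5.9e-2	0.1575	1.77	3.1e-3	8.9e-3
rs17068986	response	47416386	0.4822	0.54	1.4e-3	0.4940	0.78	3.0e-1	0.4883	0.62	1.1e-3	3.3e-3
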