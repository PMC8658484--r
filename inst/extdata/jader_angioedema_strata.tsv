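group	stratum	n11	n1plus	rr
ACE inhibitors	Total	176	1578	11.2
ACE inhibitors	Female	60	661	9.1
ACE inhibitors	Male	116	917	12.6
ACE inhibitors	<40	5	173	2.9
ACE inhibitors	40-49	3	60	5.0
ACE inhibitors	50-59	19	163	11.7
ACE inhibitors	60-69	48	333	14.4
ACE inhibitors	70-79	57	501	11.4
ACE inhibitors	80-89	43	299	14.4
ACE inhibitors	>=90	1	49	2.0
DPP-4 inhibitors	Total	101	6898	1.5
DPP-4 inhibitors	Female	44	2739	1.6
DPP-4 inhibitors	Male	57	4159	1.4
DPP-4 inhibitors	<40	1	83	1.2
DPP-4 inhibitors	40-49	7	269	2.6
DPP-4 inhibitors	50-59	21	645	3.3
DPP-4 inhibitors	60-69	22	1659	1.3
DPP-4 inhibitors	70-79	29	2342	1.2
DPP-4 inhibitors	80-89	18	1634	1.1
DPP-4 inhibitors	>=90	3	266	1.1
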