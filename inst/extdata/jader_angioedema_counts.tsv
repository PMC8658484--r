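class	drug	n11	n1plus	ic	ic025	ic975
ACE inhibitors	(class)	176	1578	2.42	2.19	2.65
ACE inhibitors	alacepril	3	21	1.47	-0.10	3.03
ACE inhibitors	benazepril	1	13	0.64	-1.54	2.82
ACE inhibitors	captopril	2	63	0.39	-1.32	2.09
ACE inhibitors	cilazapril	1	12	0.66	-1.53	2.85
ACE inhibitors	delapril	0	10	-0.29	-3.30	2.72
ACE inhibitors	enalapril	86	771	2.39	2.06	2.71
ACE inhibitors	imidapril	48	291	2.83	2.38	3.27
ACE inhibitors	lisinopril	17	133	2.28	1.55	3.00
ACE inhibitors	perindopril	6	114	1.07	-0.05	2.20
ACE inhibitors	quinapril	1	30	0.30	-1.81	2.40
ACE inhibitors	temocapril	7	105	1.35	0.29	2.40
ACE inhibitors	trandolapril	4	33	1.57	0.19	2.95
DPP-4 inhibitors	(class)	101	6898	-0.46	-0.75	-0.17
DPP-4 inhibitors	alogliptin	15	633	0.21	-0.52	0.94
DPP-4 inhibitors	anagliptin	2	212	-0.82	-2.50	0.85
DPP-4 inhibitors	linagliptin	8	736	-0.82	-1.79	0.14
DPP-4 inhibitors	omarigliptin	0	131	NA	NA	NA
DPP-4 inhibitors	saxagliptin	1	224	-1.47	-3.52	0.58
DPP-4 inhibitors	sitagliptin	26	2131	-0.71	-1.27	-0.15
DPP-4 inhibitors	teneligliptin	4	587	-1.37	-2.66	-0.07
DPP-4 inhibitors	trelagliptin	4	166	0.19	-1.12	1.50
DPP-4 inhibitors	vildagliptin	45	2183	0.02	-0.41	0.46
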