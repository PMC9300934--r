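residue	term	system	mean	sd
K579	vdw	dex	-2.21	0.93
K579	vdw	az938	-2.26	1.13
K579	vdw	pred	-2.06	0.97
K579	vdw	cor	-1.53	1.02
K579	vdw	dibc	-1.56	1.17
K579	ele	dex	-88.93	7.53
K579	ele	az938	-101.14	9.71
K579	ele	pred	-85.06	9.44
K579	ele	cor	-93.99	5.62
K579	ele	dibc	-101.54	7.41
K579	nonpolar	dex	-0.62	0.08
K579	nonpolar	az938	-0.66	0.06
K579	nonpolar	pred	-0.63	0.08
K579	nonpolar	cor	-0.71	0.07
K579	nonpolar	dibc	-0.65	0.06
K579	polar	dex	88.90	6.76
K579	polar	az938	98.77	7.66
K579	polar	pred	83.55	7.97
K579	polar	cor	90.40	4.49
K579	polar	dibc	98.76	6.20
K579	binding	dex	-2.86	1.31
K579	binding	az938	-5.29	2.06
K579	binding	pred	-4.20	1.75
K579	binding	cor	-5.83	1.41
K579	binding	dibc	-4.98	1.56
D590	vdw	dex	-0.09	0.52
D590	vdw	az938	0.17	0.87
D590	vdw	pred	0.13	0.89
D590	vdw	cor	-0.36	0.61
D590	vdw	dibc	-0.43	0.20
D590	ele	dex	-3.50	10.86
D590	ele	az938	-8.11	3.49
D590	ele	pred	-23.41	10.31
D590	ele	cor	-27.30	8.66
D590	ele	dibc	10.41	4.57
D590	nonpolar	dex	-0.08	0.06
D590	nonpolar	az938	-0.16	0.02
D590	nonpolar	pred	-0.09	0.06
D590	nonpolar	cor	-0.15	0.06
D590	nonpolar	dibc	-0.05	0.05
D590	polar	dex	2.79	9.43
D590	polar	az938	6.16	3.18
D590	polar	pred	21.92	8.57
D590	polar	cor	27.14	8.35
D590	polar	dibc	-9.54	4.56
D590	binding	dex	-0.89	1.37
D590	binding	az938	-1.95	0.76
D590	binding	pred	-1.46	1.75
D590	binding	cor	-0.68	0.71
D590	binding	dibc	0.39	0.32
E755	vdw	dex	-2.33	0.73
E755	vdw	az938	-2.54	0.97
E755	vdw	pred	-1.12	0.68
E755	vdw	cor	-2.40	0.78
E755	vdw	dibc	-1.46	0.88
E755	ele	dex	-20.95	5.65
E755	ele	az938	-32.31	3.29
E755	ele	pred	-44.89	11.18
E755	ele	cor	-62.71	5.55
E755	ele	dibc	-24.10	3.85
E755	nonpolar	dex	-0.51	0.07
E755	nonpolar	az938	-0.57	0.03
E755	nonpolar	pred	-0.40	0.06
E755	nonpolar	cor	-0.54	0.06
E755	nonpolar	dibc	-0.41	0.08
E755	polar	dex	22.40	5.33
E755	polar	az938	33.38	3.07
E755	polar	pred	45.97	10.61
E755	polar	cor	63.05	5.44
E755	polar	dibc	25.82	3.94
E755	binding	dex	-1.37	1.35
E755	binding	az938	-2.03	1.22
E755	binding	pred	-0.44	1.37
E755	binding	cor	-2.60	1.02
E755	binding	dibc	-0.14	0.82
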