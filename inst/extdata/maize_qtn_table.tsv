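trait	snp	chrom	pos	genotype	mode	effect	logp	pve
GY	gySNP1	1	215245696	T/A	Add	-0.5	4.0	6.7
GY	gySNP2	1	73916274	G/A	Add/Dom	0.92	5.3	2.1
GY	gySNP3	3	221920034	C/G	Add	-0.48	4.1	5.7
GY	gySNP4	5	209076386	G/T	Add	-0.56	4.5	12.6
GM	gmSNP1	2	1263421	A/G	Add	0.48	4.2	7.5
GM	gmSNP2	5	15548317	C/T	Add	-0.91	4.6	2.4
GM	gmSNP3	7	157333857	C/T	Add	-0.77	4.5	12.6
GM	gmSNP4	8	129615225	G/A	Add	0.58	4.0	18.7
GM	gmSNP5	9	152684176	G/A	Add	-0.51	4.1	1.6
PH	phSNP1	5	208463873	C/G	Add	9.69	4.7	9.6
PH	phSNP2	5	215535364	A/G	Add	8.39	4.0	13.2
PH	phSNP3	6	124049465	C/G	Add	9.64	4.1	8.6
PH	phSNP4	7	176596934	A/G	Add	-11.57	4.2	2.3
PH	phSNP5	8	128340728	C/A	Add/Dom	18.63	4.8	3.4
PH	phSNP6	10	147469999	C/T	Add/Dom	10.77	4.2	10.6
EH	ehSNP1	3	291054	G/A	Add	-5.03	4.1	14.2
EH	ehSNP2	6	132789720	A/G	Add	-7.04	4.4	8.8
EH	ehSNP3	7	180279662	G/A	Add	-6.88	4.8	14.9
EH	ehSNP4	9	71431208	C/A	Add/Dom	10.61	4.3	6.5
EH	ehSNP5	9	79091347	C/G	Add/Dom	-10.57	4.1	1.7
EH	ehSNP6	9	99136257	C/T	Add/Dom	-7.2	3.9	1.4
ELL	ellSNP1	1	254318451	G/A	Dom	2.04	4.0	2.2
ELL	ellSNP2	6	118971410	C/T	Add/Dom	3.5	4.1	5.4
ELL	ellSNP3	8	128340728	C/A	Add/Dom	4.97	4.0	9.6
ELW	elwSNP1	2	21687575	T/A	Dom	-0.2	4.1	1.3
ELW	elwSNP2	3	159442050	A/G	Add	0.45	4.4	8.2
ELW	elwSNP3	3	229142753	G/C	Add	-0.4	5.3	2.5
ELW	elwSNP4	5	196015158	C/T	Add/Dom	0.48	4.3	1.1
ELW	elwSNP5	5	212255011	G/A	Add	-0.36	4.1	7.6
ELW	elwSNP6	6	167994782	G/A	Add	-0.29	4.1	22.8
ELW	elwSNP7	10	107630915	T/C	Add	0.41	4.5	15.6
ELA	elaSNP1	2	195895775	G/T	Add/Dom	43.84	4.1	2.1
ELA	elaSNP2	3	163190634	C/T	Add	-20.65	3.9	9.5
ELA	elaSNP3	6	167994769	T/C	Add	-29.02	6.4	20.1
ELA	elaSNP4	7	140317639	G/A	Add	26.56	4.0	10.6
ELA	elaSNP5	7	142451671	G/A	Add	23.51	4.1	1.1
ELA	elaSNP6	9	142662042	C/G	Add	23.81	4.0	3.6
RPR_TIAG	tiagSNP1	1	244211691	T/A	Dom	2.59	4.2	1.3
RPR_TIAG	tiagSNP2	6	168202087	G/A	Add	3.2	4.3	4.2
RPR_TIAG	tiagSNP3	7	1403785	G/T	Add	-1.86	4.0	6.5
RPR_IUE	iueSNP1	1	251572876	A/T	Add/Dom	1.72	4.0	3.6
RPR_IUE	iueSNP2	6	157939881	T/C	Dom	-1.7	4.9	7.6
RPR_IUE	iueSNP3	9	140917978	T/C	Add/Dom	2.49	4.2	8.1
TBN	tbnSNP1	2	45027887	G/A	Add/Dom	1.05	4.7	1.4
TBN	tbnSNP2	2	51045430	A/C	Add/Dom	1.24	5.1	6.0
TBN	tbnSNP3	4	186665498	G/A	Add/Dom	-1.06	5.4	3.1
TBN	tbnSNP4	4	189101304	A/T	Add/Dom	-0.98	5.3	2.2
TBN	tbnSNP5	5	201203454	C/T	Dom	0.62	4.5	5.6
TBN	tbnSNP6	6	134143465	A/T	Dom	-0.6	4.0	2.7
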