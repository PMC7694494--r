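name	kind	region	len	n_exons	strand
psbA	PCG	LSC	1062	1	-
trnK-UUU	tRNA	LSC	72	2	-
matK	PCG	LSC	1530	1	-
rps16	PCG	LSC	261	2	-
trnQ-UUG	tRNA	LSC	72	1	-
psbK	PCG	LSC	186	1	+
psbI	PCG	LSC	111	1	+
trnS-GCU	tRNA	LSC	88	1	-
trnG-UCC	tRNA	LSC	71	2	+
trnR-UCU	tRNA	LSC	72	1	+
atpA	PCG	LSC	1524	1	-
atpF	PCG	LSC	555	2	-
atpH	PCG	LSC	246	1	-
atpI	PCG	LSC	744	1	-
rps2	PCG	LSC	711	1	-
rpoC2	PCG	LSC	4140	1	-
rpoC1	PCG	LSC	2043	2	-
rpoB	PCG	LSC	3213	1	-
trnC-GCA	tRNA	LSC	71	1	+
petN	PCG	LSC	90	1	+
psbM	PCG	LSC	105	1	-
trnD-GUC	tRNA	LSC	74	1	-
trnY-GUA	tRNA	LSC	84	1	-
trnE-UUC	tRNA	LSC	73	1	-
trnT-GGU	tRNA	LSC	72	1	+
psbD	PCG	LSC	1062	1	+
psbC	PCG	LSC	1386	1	+
trnS-UGA	tRNA	LSC	93	1	-
psbZ	PCG	LSC	189	1	+
trnG-GCC	tRNA	LSC	71	1	+
trnfM-CAU	tRNA	LSC	74	1	-
rps14	PCG	LSC	303	1	-
psaB	PCG	LSC	2205	1	-
psaA	PCG	LSC	2253	1	-
ycf3	PCG	LSC	507	3	-
trnS-GGA	tRNA	LSC	87	1	-
rps4	PCG	LSC	606	1	-
trnT-UGU	tRNA	LSC	73	1	-
trnL-UAA	tRNA	LSC	85	2	+
trnF-GAA	tRNA	LSC	73	1	+
ndhJ	PCG	LSC	480	1	-
ndhK	PCG	LSC	678	1	-
ndhC	PCG	LSC	363	1	-
trnV-UAC	tRNA	LSC	72	2	-
trnM-CAU	tRNA	LSC	73	1	+
atpE	PCG	LSC	402	1	+
atpB	PCG	LSC	1497	1	-
rbcL	PCG	LSC	1428	1	+
accD	PCG	LSC	1467	1	+
psaI	PCG	LSC	111	1	+
ycf4	PCG	LSC	555	1	+
cemA	PCG	LSC	690	1	+
petA	PCG	LSC	963	1	+
psbJ	PCG	LSC	123	1	-
psbL	PCG	LSC	117	1	-
psbF	PCG	LSC	120	1	-
psbE	PCG	LSC	252	1	-
petL	PCG	LSC	96	1	+
petG	PCG	LSC	114	1	+
trnW-CCA	tRNA	LSC	74	1	-
trnP-UGG	tRNA	LSC	74	1	-
psaJ	PCG	LSC	135	1	+
rpl33	PCG	LSC	201	1	+
rps18	PCG	LSC	306	1	+
rpl20	PCG	LSC	354	1	-
clpP	PCG	LSC	591	3	-
psbB	PCG	LSC	1527	1	+
psbT	PCG	LSC	108	1	+
psbN	PCG	LSC	132	1	-
psbH	PCG	LSC	222	1	+
petB	PCG	LSC	648	2	+
petD	PCG	LSC	483	2	+
rpoA	PCG	LSC	1014	1	-
rps11	PCG	LSC	417	1	-
rpl36	PCG	LSC	114	1	-
infA	PCG	LSC	234	1	-
rps8	PCG	LSC	405	1	-
rpl14	PCG	LSC	369	1	-
rpl16	PCG	LSC	411	2	-
rps3	PCG	LSC	657	1	-
rpl22	PCG	LSC	477	1	-
rps19	PCG	LSC	279	1	-
trnH-GUG	tRNA	LSC	75	1	-
rpl2	PCG	IR	1491	2	+
rpl23	PCG	IR	282	1	+
trnI-CAU	tRNA	IR	74	1	+
ycf2	PCG	IR	6837	1	+
ycf15	PCG	IR	288	1	+
trnL-CAA	tRNA	IR	81	1	-
ndhB	PCG	IR	1533	2	-
rps7	PCG	IR	468	1	-
rps12	PCG	IR	372	2	-
trnV-GAC	tRNA	IR	72	1	+
rrn16	rRNA	IR	1491	1	+
trnI-GAU	tRNA	IR	72	2	+
trnA-UGC	tRNA	IR	73	2	+
rrn23	rRNA	IR	2810	1	+
rrn4.5	rRNA	IR	103	1	+
rrn5	rRNA	IR	121	1	+
trnR-ACG	tRNA	IR	74	1	-
trnN-GUU	tRNA	IR	72	1	-
ndhF	PCG	SSC	2241	1	-
rpl32	PCG	SSC	174	1	+
trnL-UAG	tRNA	SSC	80	1	+
ccsA	PCG	SSC	966	1	+
ndhD	PCG	SSC	1503	1	-
psaC	PCG	SSC	246	1	-
ndhE	PCG	SSC	306	1	-
ndhG	PCG	SSC	531	1	-
ndhI	PCG	SSC	543	1	-
ndhA	PCG	SSC	1092	2	-
ndhH	PCG	SSC	1182	1	-
rps15	PCG	SSC	273	1	-
ycf1	PCG	SSC	5532	1	+
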