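##gff-version 3
ctgA	hand	gene	101	429	.	+	.	ID=t01_g
ctgA	hand	mRNA	101	429	.	+	.	ID=t01;Parent=t01_g
ctgA	hand	CDS	101	130	.	+	0	ID=t01.c1;Parent=t01
ctgA	hand	CDS	200	211	.	+	0	ID=t01.c2;Parent=t01
ctgA	hand	CDS	300	311	.	+	0	ID=t01.c3;Parent=t01
ctgA	hand	CDS	400	429	.	+	0	ID=t01.c4;Parent=t01
ctgA	hand	gene	930	1241	.	-	.	ID=t02_g
ctgA	hand	mRNA	930	1241	.	-	.	ID=t02;Parent=t02_g
ctgA	hand	CDS	930	959	.	-	0	ID=t02.c1;Parent=t02
ctgA	hand	CDS	1030	1041	.	-	0	ID=t02.c2;Parent=t02
ctgA	hand	CDS	1130	1141	.	-	0	ID=t02.c3;Parent=t02
ctgA	hand	CDS	1212	1241	.	-	0	ID=t02.c4;Parent=t02
ctgA	hand	gene	1742	1996	.	+	.	ID=t03_g
ctgA	hand	mRNA	1742	1996	.	+	.	ID=t03;Parent=t03_g
ctgA	hand	CDS	1742	1751	.	+	0	ID=t03.c1;Parent=t03
ctgA	hand	CDS	1802	1806	.	+	2	ID=t03.c2;Parent=t03
ctgA	hand	CDS	1868	1874	.	+	0	ID=t03.c3;Parent=t03
ctgA	hand	CDS	1922	1929	.	+	2	ID=t03.c4;Parent=t03
ctgA	hand	CDS	1985	1996	.	+	0	ID=t03.c5;Parent=t03
ctgA	hand	gene	2497	2831	.	-	.	ID=t04_g
ctgA	hand	mRNA	2497	2831	.	-	.	ID=t04;Parent=t04_g
ctgA	hand	CDS	2497	2508	.	-	0	ID=t04.c1;Parent=t04
ctgA	hand	CDS	2584	2597	.	-	2	ID=t04.c2;Parent=t04
ctgA	hand	CDS	2642	2647	.	-	2	ID=t04.c3;Parent=t04
ctgA	hand	CDS	2711	2720	.	-	0	ID=t04.c4;Parent=t04
ctgA	hand	CDS	2773	2779	.	-	1	ID=t04.c5;Parent=t04
ctgA	hand	CDS	2821	2831	.	-	0	ID=t04.c6;Parent=t04
ctgB	hand	gene	101	955	.	+	.	ID=t05_g
ctgB	hand	mRNA	101	955	.	+	.	ID=t05;Parent=t05_g
ctgB	hand	CDS	101	200	.	+	0	ID=t05.c1;Parent=t05
ctgB	hand	CDS	281	300	.	+	2	ID=t05.c2;Parent=t05
ctgB	hand	CDS	392	411	.	+	0	ID=t05.c3;Parent=t05
ctgB	hand	CDS	514	533	.	+	1	ID=t05.c4;Parent=t05
ctgB	hand	CDS	619	638	.	+	2	ID=t05.c5;Parent=t05
ctgB	hand	CDS	716	735	.	+	0	ID=t05.c6;Parent=t05
ctgB	hand	CDS	856	955	.	+	1	ID=t05.c7;Parent=t05
ctgB	hand	gene	1456	1940	.	-	.	ID=t06_g
ctgB	hand	mRNA	1456	1940	.	-	.	ID=t06;Parent=t06_g
ctgB	hand	CDS	1456	1464	.	-	0	ID=t06.c1;Parent=t06
ctgB	hand	CDS	1564	1575	.	-	0	ID=t06.c2;Parent=t06
ctgB	hand	CDS	1726	1731	.	-	0	ID=t06.c3;Parent=t06
ctgB	hand	CDS	1932	1940	.	-	0	ID=t06.c4;Parent=t06
ctgB	hand	gene	2441	2719	.	+	.	ID=t07_g
ctgB	hand	mRNA	2441	2719	.	+	.	ID=t07;Parent=t07_g
ctgB	hand	CDS	2441	2453	.	+	0	ID=t07.c1;Parent=t07
ctgB	hand	CDS	2520	2533	.	+	2	ID=t07.c2;Parent=t07
ctgB	hand	CDS	2606	2621	.	+	0	ID=t07.c3;Parent=t07
ctgB	hand	CDS	2703	2719	.	+	2	ID=t07.c4;Parent=t07
ctgB	hand	gene	3220	3507	.	-	.	ID=t08_g
ctgB	hand	mRNA	3220	3507	.	-	.	ID=t08;Parent=t08_g
ctgB	hand	CDS	3220	3237	.	-	0	ID=t08.c1;Parent=t08
ctgB	hand	CDS	3308	3320	.	-	1	ID=t08.c2;Parent=t08
ctgB	hand	CDS	3382	3392	.	-	0	ID=t08.c3;Parent=t08
ctgB	hand	CDS	3445	3454	.	-	1	ID=t08.c4;Parent=t08
ctgB	hand	CDS	3500	3507	.	-	0	ID=t08.c5;Parent=t08
ctgB	hand	gene	4008	4544	.	+	.	ID=t09_g
ctgB	hand	mRNA	4008	4544	.	+	.	ID=t09;Parent=t09_g
ctgB	hand	CDS	4008	4028	.	+	0	ID=t09.c1;Parent=t09
ctgB	hand	CDS	4119	4151	.	+	0	ID=t09.c2;Parent=t09
ctgB	hand	CDS	4236	4247	.	+	0	ID=t09.c3;Parent=t09
ctgB	hand	CDS	4325	4333	.	+	0	ID=t09.c4;Parent=t09
ctgB	hand	CDS	4399	4428	.	+	0	ID=t09.c5;Parent=t09
ctgB	hand	CDS	4530	4544	.	+	0	ID=t09.c6;Parent=t09
ctgB	hand	gene	5045	5563	.	-	.	ID=t10_g
ctgB	hand	mRNA	5045	5563	.	-	.	ID=t10;Parent=t10_g
ctgB	hand	CDS	5045	5058	.	-	2	ID=t10.c1;Parent=t10
ctgB	hand	CDS	5158	5173	.	-	0	ID=t10.c2;Parent=t10
ctgB	hand	CDS	5262	5275	.	-	2	ID=t10.c3;Parent=t10
ctgB	hand	CDS	5353	5365	.	-	0	ID=t10.c4;Parent=t10
ctgB	hand	CDS	5432	5443	.	-	0	ID=t10.c5;Parent=t10
ctgB	hand	CDS	5499	5509	.	-	2	ID=t10.c6;Parent=t10
ctgB	hand	CDS	5554	5563	.	-	0	ID=t10.c7;Parent=t10
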