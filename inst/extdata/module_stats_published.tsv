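Module	NP	IntraMI	InterMI	TotInt	MTraffic
1	11	10	8	18	38
2	19	18	21	39	36
3	52	52	41	93	102
4	132	153	122	275	262
5	437	587	391	978	872
6	252	268	212	480	502
7	127	148	105	253	252
8	265	317	183	500	528
9	13	15	7	22	24
10	507	1589	610	2199	1012
11	5	4	1	5	8
12	6	5	7	12	10
13	39	49	11	60	82.16
14	65	84	41	125	128
15	118	131	59	190	234
16	460	863	307	1170	918
17	3	2	2	4	4
18	7	6	2	8	12
19	5	4	2	6	8
20	4	3	1	4	6
21	5	4	1	5	8
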