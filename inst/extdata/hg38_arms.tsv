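arm	chromosome	start	end
1p	1	1	123400000
1q	1	123400001	248956422
2p	2	1	93900000
2q	2	93900001	242193529
3p	3	1	90900000
3q	3	90900001	198295559
4p	4	1	5e+07
4q	4	50000001	190214555
5p	5	1	48800000
5q	5	48800001	181538259
6p	6	1	59800000
6q	6	59800001	170805979
7p	7	1	60100000
7q	7	60100001	159345973
8p	8	1	45200000
8q	8	45200001	145138636
9p	9	1	4.3e+07
9q	9	43000001	138394717
10p	10	1	39800000
10q	10	39800001	133797422
11p	11	1	53400000
11q	11	53400001	135086622
12p	12	1	35500000
12q	12	35500001	133275309
13q	13	17700001	114364328
14q	14	17200001	107043718
15q	15	19000001	101991189
16p	16	1	36800000
16q	16	36800001	90338345
17p	17	1	25100000
17q	17	25100001	83257441
18p	18	1	18500000
18q	18	18500001	80373285
19p	19	1	26200000
19q	19	26200001	58617616
20p	20	1	28100000
20q	20	28100001	64444167
21q	21	12000001	46709983
22q	22	15000001	50818468
Xp	X	1	6.1e+07
Xq	X	61000001	156040895
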