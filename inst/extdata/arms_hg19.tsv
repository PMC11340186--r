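arm_id	chrom	start	end
1p	chr1	0	1.25e+08
1q	chr1	1.25e+08	249250000
2p	chr2	0	93300000
2q	chr2	93300000	243200000
3p	chr3	0	9.1e+07
3q	chr3	9.1e+07	1.98e+08
4p	chr4	0	50400000
4q	chr4	50400000	191150000
5p	chr5	0	48400000
5q	chr5	48400000	180920000
6p	chr6	0	6.1e+07
6q	chr6	6.1e+07	171120000
7p	chr7	0	59900000
7q	chr7	59900000	159140000
8p	chr8	0	45600000
8q	chr8	45600000	146360000
9p	chr9	0	4.9e+07
9q	chr9	4.9e+07	141210000
10p	chr10	0	40200000
10q	chr10	40200000	135530000
11p	chr11	0	53700000
11q	chr11	53700000	1.35e+08
12p	chr12	0	35800000
12q	chr12	35800000	133850000
13p	chr13	0	17900000
13q	chr13	17900000	115170000
14p	chr14	0	17600000
14q	chr14	17600000	107350000
15p	chr15	0	1.9e+07
15q	chr15	1.9e+07	102530000
16p	chr16	0	36600000
16q	chr16	36600000	90350000
17p	chr17	0	2.4e+07
17q	chr17	2.4e+07	81200000
18p	chr18	0	17200000
18q	chr18	17200000	78080000
19p	chr19	0	26500000
19q	chr19	26500000	59130000
20p	chr20	0	27500000
20q	chr20	27500000	63030000
21p	chr21	0	13200000
21q	chr21	13200000	48130000
22p	chr22	0	14700000
22q	chr22	14700000	51300000
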