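i	j	tanimoto
1	2	0.000000
1	3	0.153846
1	4	0.035714
1	5	0.107143
1	6	0.090909
1	7	0.030303
1	8	0.062500
1	9	0.066667
1	10	0.052632
1	11	0.000000
1	12	0.000000
1	13	0.052632
1	14	0.000000
1	15	0.000000
1	16	0.200000
1	17	0.250000
1	18	0.090909
1	19	0.000000
1	20	0.000000
2	3	0.125000
2	4	0.040000
2	5	0.076923
2	6	0.050000
2	7	0.068966
2	8	0.272727
2	9	0.300000
2	10	0.214286
2	11	0.333333
2	12	0.272727
2	13	0.214286
2	14	0.250000
2	15	0.214286
2	16	0.000000
2	17	0.000000
2	18	0.000000
2	19	0.066667
2	20	0.000000
3	4	0.119048
3	5	0.225000
3	6	0.235294
3	7	0.155556
3	8	0.250000
3	9	0.259259
3	10	0.266667
3	11	0.100000
3	12	0.206897
3	13	0.407407
3	14	0.192308
3	15	0.187500
3	16	0.250000
3	17	0.064516
3	18	0.111111
3	19	0.027778
3	20	0.000000
4	5	0.170732
4	6	0.108108
4	7	0.186047
4	8	0.062500
4	9	0.100000
4	10	0.121212
4	11	0.103448
4	12	0.062500
4	13	0.088235
4	14	0.071429
4	15	0.057143
4	16	0.074074
4	17	0.000000
4	18	0.035714
4	19	0.125000
4	20	0.000000
5	6	0.228571
5	7	0.104167
5	8	0.200000
5	9	0.166667
5	10	0.147059
5	11	0.096774
5	12	0.125000
5	13	0.218750
5	14	0.142857
5	15	0.147059
5	16	0.148148
5	17	0.096774
5	18	0.107143
5	19	0.055556
5	20	0.000000
6	7	0.095238
6	8	0.318182
6	9	0.217391
6	10	0.185185
6	11	0.038462
6	12	0.115385
6	13	0.230769
6	14	0.136364
6	15	0.103448
6	16	0.263158
6	17	0.038462
6	18	0.142857
6	19	0.068966
6	20	0.000000
7	8	0.114286
7	9	0.151515
7	10	0.166667
7	11	0.233333
7	12	0.114286
7	13	0.135135
7	14	0.129032
7	15	0.105263
7	16	0.030303
7	17	0.000000
7	18	0.000000
7	19	0.138889
7	20	0.068966
8	9	0.400000
8	10	0.388889
8	11	0.176471
8	12	0.375000
8	13	0.388889
8	14	0.384615
8	15	0.315789
8	16	0.062500
8	17	0.052632
8	18	0.062500
8	19	0.043478
8	20	0.000000
9	10	0.411765
9	11	0.187500
9	12	0.400000
9	13	0.333333
9	14	0.416667
9	15	0.333333
9	16	0.066667
9	17	0.000000
9	18	0.000000
9	19	0.045455
9	20	0.000000
10	11	0.150000
10	12	0.315789
10	13	0.272727
10	14	0.400000
10	15	0.333333
10	16	0.052632
10	17	0.000000
10	18	0.000000
10	19	0.038462
10	20	0.000000
11	12	0.176471
11	13	0.150000
11	14	0.142857
11	15	0.150000
11	16	0.000000
11	17	0.000000
11	18	0.000000
11	19	0.222222
11	20	0.000000
12	13	0.315789
12	14	0.384615
12	15	0.315789
12	16	0.000000
12	17	0.000000
12	18	0.062500
12	19	0.043478
12	20	0.000000
13	14	0.312500
13	15	0.272727
13	16	0.176471
13	17	0.045455
13	18	0.176471
13	19	0.038462
13	20	0.000000
14	15	0.400000
14	16	0.000000
14	17	0.000000
14	18	0.000000
14	19	0.052632
14	20	0.000000
15	16	0.000000
15	17	0.045455
15	18	0.000000
15	19	0.038462
15	20	0.000000
16	17	0.071429
16	18	0.333333
16	19	0.000000
16	20	0.000000
17	18	0.071429
17	19	0.047619
17	20	0.000000
18	19	0.000000
18	20	0.000000
19	20	0.000000
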