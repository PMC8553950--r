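n_orfs	n_target	is_target
0	0	FALSE
1	0	FALSE
1	1	TRUE
2	0	FALSE
2	1	FALSE
2	2	TRUE
3	0	FALSE
3	1	FALSE
3	2	FALSE
3	3	TRUE
4	0	FALSE
4	1	FALSE
4	2	FALSE
4	3	TRUE
4	4	TRUE
5	0	FALSE
5	1	FALSE
5	2	FALSE
5	3	FALSE
5	4	TRUE
5	5	TRUE
6	0	FALSE
6	1	FALSE
6	2	FALSE
6	3	FALSE
6	4	TRUE
6	5	TRUE
6	6	TRUE
7	0	FALSE
7	1	FALSE
7	2	FALSE
7	3	FALSE
7	4	TRUE
7	5	TRUE
7	6	TRUE
7	7	TRUE
8	0	FALSE
8	1	FALSE
8	2	FALSE
8	3	FALSE
8	4	FALSE
8	5	TRUE
8	6	TRUE
8	7	TRUE
8	8	TRUE
9	0	FALSE
9	1	FALSE
9	2	FALSE
9	3	FALSE
9	4	FALSE
9	5	TRUE
9	6	TRUE
9	7	TRUE
9	8	TRUE
9	9	TRUE
10	0	FALSE
10	1	FALSE
10	2	FALSE
10	3	FALSE
10	4	FALSE
10	5	FALSE
10	6	TRUE
10	7	TRUE
10	8	TRUE
10	9	TRUE
10	10	TRUE
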