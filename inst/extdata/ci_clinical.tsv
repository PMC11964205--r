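id	age	onset_age	deafness_duration	implantation_age	ci_use_years
1	22	pre-linguistic	8	8	14
2	22	2	2	4	18
3	43	6	30	36	7
4	51	37	2	39	12
5	19	7	3	10	9
6	29	2	20	22	7
7	63	40	20	60	3
9	35	24	2	26	9
10	49	42	1	43	6
11	56	49	4	53	3
12	33	pre-linguistic	16	16	17
15	65	31	32	63	2
16	47	33	6	39	8
18	41	21	3	24	17
19	57	20	33	53	4
20	43	19	19	38	5
21	20	1	18	19	1
22	58	48	7	55	3
23	58	40	15	55	3
25	52	25	26	51	1
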