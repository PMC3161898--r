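component	capacity	0	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37	38	39	40	41	42	43	44	45
pi-pp	1	1	0	0	0	0	0	0	0	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
pi-cp	1	0	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
po-pp	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Pst-P	1	1	1	0	0	0	0	0	0	0	1	1	1	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0	0	0	1	0	0	1	0	0	0
Pst	1	0	0	1	1	1	1	1	1	1	0	0	0	0	1	1	1	1	1	1	1	1	0	1	1	1	1	1	0	0	0	0	1	0	1	1	0	1	1	1	0	1	1	0	1	1	1
PhoU-I	1	1	1	1	0	0	0	0	0	0	0	1	1	1	1	0	0	0	0	0	0	0	1	1	0	0	0	0	1	1	1	0	0	1	1	0	1	1	0	0	1	1	0	1	1	0	0
PhoU-A	1	0	0	0	1	1	1	1	1	1	1	0	0	0	0	1	1	1	1	1	1	1	0	0	1	1	1	1	0	0	0	0	0	0	0	1	0	0	1	1	0	0	1	0	0	1	1
PhoR	1	1	1	1	1	0	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1	0	1	1	1	0	1	0	1	1	1	1	1	0	0	0	1	1	1	0	1	1	1	1	1	1	0
PhoR-P	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	1	0	1	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1
PhoR-S	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	1	1	1	1
PhoB	1	1	1	1	1	1	0	0	0	0	0	0	1	1	1	1	1	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1	1	1	1	1	0	0	0	0	1	1	1	1	1	1	1
PhoB-P	1	0	0	0	0	0	1	1	1	1	1	1	0	0	0	0	0	1	1	1	1	1	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
PhoB-S	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0
PhoA-T	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
PhoA	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
PhoA-pp	1	0	0	0	0	0	0	0	1	1	1	1	1	0	0	0	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
.experiment		exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp1	exp2	exp2	exp2	exp2	exp2	exp2	exp2	exp2	exp2	exp3	exp3	exp3	exp3	exp3	exp3	exp4	exp5	exp6	exp7	exp7	exp8	exp8	exp8	exp9	exp9	exp9	exp9	exp10	exp10	exp10	exp11	exp11	exp11	exp11
.terminal		0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1	1	1	1	0	1	0	0	1	0	0	0	1	0	0	1	0	0	0	1
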