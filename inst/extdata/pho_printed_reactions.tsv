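component	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19
pi-pp	-1	0	0	0	0	0	0	1	0	0	0	-1	0	0	0	0	0	0	1
pi-cp	1	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
po-pp	0	0	0	0	0	0	0	-1	0	0	0	0	0	0	0	0	0	-1	0
Pst-P	0	-1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0
Pst	0	1	0	0	0	0	0	0	-1	0	0	0	0	0	0	0	0	0	0
PhoU-I	0	0	-1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
PhoU-A	0	0	1	0	0	0	0	0	0	-1	0	0	0	0	0	0	0	0	0
PhoR	0	0	0	-1	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0
PhoR-P	0	0	0	1	-1	0	0	0	0	0	0	0	0	-1	0	0	0	0	0
PhoR-S	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
PhoB	0	0	0	0	-1	0	0	0	0	0	1	0	0	0	-1	0	0	0	0
PhoB-P	0	0	0	0	1	0	0	0	0	0	-1	0	0	0	1	0	0	0	0
PhoB-S	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
PhoA-T	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
PhoA	0	0	0	0	0	1	-1	0	0	0	0	0	0	0	0	-1	0	0	0
PhoA-pp	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0
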