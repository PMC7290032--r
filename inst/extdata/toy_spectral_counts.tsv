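accession	gene	pep_bait_r1	pep_ctrl_r1	sc_bait_r1	sc_ctrl_r1
P01	GENE1	4	2	30	5
P02	GENE2	2	1	9	3
P03	GENE3	2	1	8	3
P04	GENE4	1	0	50	0
P05	GENE5	3	0	12	0
P06-1	GENE6	2	1	10	2
P06-2	GENE6	2	1	7	2
P07-1	GENE7	2	1	5	2
P07-2	GENE7	3	1	9	2
P08	PC	5	3	100	1
P09	GENE9	2	0	0	0
P10	GENE10	2	1	6	2
P11	GENE11	6	4	40	10
P12	GENE12	2	2	5	5
P13	GENE13	2	1	2	1
P14	GENE14	1	0	3	0
P15	GENE15	3	2	10	4
P16	GENE16	2	1	11	4
P17	GENE17	2	1	2	1
P18	GENE18	0	1	0	3
P19	GENE19	2	2	12	5
P20	GENE20	2	2	14	5
P21	GENE21	1	1	9	1
P22	GENE22	2	1	3	2
P23	GENE23	3	2	7	3
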