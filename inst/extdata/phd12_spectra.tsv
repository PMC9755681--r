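peptide	AAA	ATC	AGG	ACT	ACG
FIPAQLHFHWRS	0	0	1400	1800	700
HMGRHMHEGASS	2	140	180	80	115
WPLFHFHERGSH	2	500	80	48	380
HYTHTHQYTYSM	1	260	52	30	250
QHFHIGESGSLL	2	190	34	20	78
KLWVIPQSGRTA	1	85	24	10	52
NDVRSGWQTYLK	1	60	15	5	36
SMTWNAKEPGVQ	0	50	10	3	30
RQEYWSLGNKAV	0	32	6	2	15
GAVTLSNQWKRD	0	25	4	2	10
ALWPPNLHAWVP	72	360	120	0	170
AHSANNFDVKGI	470	100	30	0	62
TPMVERNYNAAD	340	70	20	0	44
MPLMSEPALEML	265	40	12	0	25
YSAHNYIGDSGP	215	30	8	0	20
LNTPQGAWSVKE	175	20	3	0	6
EKSGVYWPQLNT	145	15	2	0	4
VWGKQNSLTAEP	120	10	0	0	2
TQNPSGLWVAKE	100	8	0	0	1
GQDFVSNLWTAK	89	5	0	0	0
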