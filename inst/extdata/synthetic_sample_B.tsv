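CHR	START	END	cell5	cell7	cell12	cell16	cell19	cell22	cell32	cell38	cell40	cell50	cell51	cell54	cell55	cell58	cell59	cell65	cell66	cell67	cell68	cell69	cell78	cell79
chr1	1	500000	2	2	2	2	2	2	0	2	3	3	3	2	2	0	0	2	2	2	3	3	0	0
chr1	500001	1000000	2	2	2	2	3	2	0	2	3	3	3	2	2	0	0	2	2	2	3	3	0	0
chr1	1000001	1500000	2	2	2	2	2	2	0	2	3	3	3	2	2	0	0	2	2	2	3	3	0	0
chr1	1500001	2000000	2	2	2	2	2	2	0	2	2	2	2	2	2	0	0	2	2	2	2	2	0	0
chr1	2000001	2500000	2	2	2	2	2	2	2	2	2	2	2	3	3	2	2	2	2	2	2	2	2	2
chr1	2500001	3000000	2	2	2	2	2	2	6	2	2	2	2	7	7	6	6	2	2	3	2	2	6	6
chr1	3000001	3500000	2	2	2	2	2	2	0	2	2	2	2	2	2	0	0	2	2	3	2	2	0	0
chr1	3500001	4000000	2	2	2	2	2	2	0	2	2	2	2	2	2	0	0	2	2	3	2	3	0	0
chr1	4000001	4500000	2	2	2	2	2	2	0	2	2	2	2	2	2	0	0	2	2	3	2	3	0	0
chr1	4500001	5000000	2	2	2	2	2	2	0	2	2	2	2	2	2	0	0	2	2	2	2	3	0	0
chr1	5000001	5500000	2	2	2	1	2	2	0	2	2	2	2	1	1	0	0	2	2	2	2	2	0	0
chr1	5500001	6000000	2	2	2	1	3	2	0	2	2	2	2	1	1	0	0	2	2	2	2	2	0	0
chr1	6000001	6500000	2	2	2	1	3	2	0	2	2	2	2	1	1	0	0	2	2	2	2	2	0	0
chr1	6500001	7000000	2	2	3	2	3	3	0	3	2	2	2	2	2	0	0	3	3	3	2	2	0	0
chr1	7000001	7500000	2	2	3	2	3	3	0	3	2	2	2	2	2	0	0	3	3	3	2	2	0	0
chr1	7500001	8000000	2	2	3	3	3	3	0	3	2	2	2	3	3	1	1	3	3	3	2	2	1	1
chr1	8000001	8500000	2	2	3	3	3	3	0	3	2	2	2	3	3	1	1	3	3	3	2	2	1	1
chr1	8500001	9000000	2	2	3	3	3	3	0	3	2	2	2	3	3	1	1	3	3	3	2	2	1	1
chr1	9000001	9500000	2	0	2	2	2	2	0	2	1	1	1	2	2	0	0	2	2	2	1	1	0	0
chr1	9500001	10000000	2	0	2	2	2	2	0	2	1	0	1	2	2	0	0	2	2	2	1	1	0	0
chr1	10000001	10500000	2	0	1	1	2	1	0	1	3	0	1	1	1	0	0	1	1	1	1	1	0	0
chr1	10500001	11000000	2	2	1	1	2	1	0	1	1	0	1	1	1	0	0	1	1	1	1	1	0	0
chr1	11000001	11500000	2	2	1	1	1	1	0	1	1	0	1	1	1	0	0	1	1	1	1	1	0	0
chr1	11500001	12000000	2	2	2	2	2	2	2	2	2	1	2	3	3	2	2	2	2	2	2	2	2	2
chr1	12000001	12500000	2	2	2	3	2	2	2	2	2	1	2	3	3	2	2	2	2	2	2	2	2	2
chr1	12500001	13000000	2	2	2	3	2	4	2	4	2	2	2	3	3	2	2	4	4	4	2	2	2	2
chr1	13000001	13500000	2	2	2	3	2	4	2	4	2	2	2	3	3	2	2	4	4	4	2	2	2	2
chr1	13500001	14000000	2	2	2	3	2	2	2	2	2	2	2	3	3	2	2	2	2	2	2	2	12	2
chr1	14000001	14500000	2	2	2	2	2	2	2	2	2	2	2	3	3	2	2	2	2	2	2	2	12	2
chr1	14500001	15000000	2	2	2	2	2	2	2	2	2	2	1	3	3	2	2	2	3	2	2	2	12	2
chr1	15000001	15500000	2	2	2	2	2	2	2	2	2	2	1	3	3	2	2	2	3	2	2	2	12	2
chr1	15500001	16000000	2	2	2	2	2	2	3	2	2	2	1	3	3	2	2	2	3	2	2	2	12	2
chr1	16000001	16500000	2	2	2	2	2	2	3	2	2	2	1	3	3	2	2	2	3	2	2	2	12	2
chr1	16500001	17000000	2	2	2	2	2	2	3	2	2	2	1	3	3	2	2	2	3	2	0	0	12	2
chr1	17000001	17500000	2	2	2	2	2	2	3	2	2	2	1	3	3	2	2	2	2	2	0	0	12	2
chr1	17500001	18000000	2	2	2	2	2	2	3	2	2	2	1	3	3	2	2	2	2	2	0	0	12	2
chr1	18000001	18500000	2	2	2	2	2	2	3	2	2	2	1	2	2	2	2	2	2	2	0	0	12	2
chr1	18500001	19000000	2	2	2	2	2	2	3	2	2	2	1	2	2	2	2	2	2	2	0	0	2	2
chr1	19000001	19500000	3	3	3	3	3	3	4	3	3	3	2	3	3	3	3	3	3	3	1	1	3	3
chr1	19500001	20000000	3	3	3	3	3	3	4	3	3	3	2	3	3	3	3	3	3	3	1	1	3	3
chr2	1	500000	2	2	2	2	2	2	2	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2
chr2	500001	1000000	2	2	2	2	2	2	2	3	2	2	2	2	2	2	2	2	2	2	2	2	3	2
chr2	1000001	1500000	2	6	2	0	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	2
chr2	1500001	2000000	2	6	2	0	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	2
chr2	2000001	2500000	2	6	2	2	2	2	1	2	2	2	2	1	1	1	1	2	2	2	2	2	2	1
chr2	2500001	3000000	2	6	2	2	2	2	1	2	2	2	2	1	1	1	1	2	2	2	2	2	1	1
chr2	3000001	3500000	2	6	2	2	2	2	1	2	2	2	2	1	1	1	1	2	2	2	2	2	1	1
chr2	3500001	4000000	2	6	2	2	2	2	0	2	2	2	2	1	1	0	0	2	2	2	2	2	0	0
chr2	4000001	4500000	2	6	2	2	2	2	2	2	2	2	2	2	2	1	2	2	2	2	2	2	2	2
chr2	4500001	5000000	2	6	2	2	2	2	2	2	2	2	2	2	2	1	2	2	2	2	2	2	2	2
chr2	5000001	5500000	2	6	2	2	2	2	2	2	2	2	2	1	1	1	2	2	2	2	2	2	2	2
chr2	5500001	6000000	2	6	2	2	0	2	2	2	0	0	0	1	1	1	2	2	2	2	0	0	2	2
chr2	6000001	6500000	2	6	2	2	0	2	2	2	0	0	0	2	2	2	3	2	2	2	0	0	3	3
chr2	6500001	7000000	3	6	2	2	0	2	2	0	0	0	0	2	2	2	3	0	0	0	0	0	3	3
chr2	7000001	7500000	3	6	2	2	0	2	2	0	0	0	0	2	2	3	3	0	0	0	0	0	3	3
chr2	7500001	8000000	3	6	2	2	0	2	2	0	0	0	0	2	2	3	3	0	0	0	0	0	3	3
chr2	8000001	8500000	3	2	2	2	0	2	2	0	0	0	0	2	2	3	3	0	0	0	0	0	3	3
chr2	8500001	9000000	3	1	1	1	1	1	1	3	0	0	0	1	1	2	2	3	3	3	0	0	2	2
chr2	9000001	9500000	3	1	1	1	1	1	1	3	1	0	0	1	1	2	2	3	3	3	1	1	2	2
chr2	9500001	10000000	3	2	2	2	2	2	2	4	2	0	0	2	2	3	3	4	4	4	2	2	3	3
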