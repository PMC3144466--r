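element	offset	mass	abundance
C	0	12.0	0.9893
C	1	13.0033548378	0.0107
H	0	1.0078250319	0.999885
H	1	2.0141017781	0.000115
N	0	14.0030740052	0.996337
N	1	15.0001088984	0.003663
O	0	15.9949146221	0.99757
O	1	16.9991315	0.00038
O	2	17.9991604	0.00205
S	0	31.97207069	0.9493
S	1	32.9714585	0.0076
S	2	33.96786683	0.0429
S	4	35.96708088	0.0002
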