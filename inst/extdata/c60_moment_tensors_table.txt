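rank	label	indices	value
0	G0	-	60
1	G1	1	0
1	G2	2	2e-05
1	G3	3	2e-05
2	G4	11	251.57483
2	G5	12	0.00871
2	G6	13	0.02755
2	G7	22	251.57513
2	G8	23	-0.03941
2	G9	33	251.6387
3	G10	111	0.0019
3	G11	112	0.00288
3	G12	113	-0.00735
3	G13	122	-0.00382
3	G14	123	-0.00095
3	G15	133	0.00172
3	G16	222	0.0111
3	G17	223	-0.0065
3	G18	233	-0.01328
3	G19	333	0.01462
4	G20	1111	1898.65174
4	G21	1112	-0.08173
4	G22	1113	0.2394
4	G23	1122	632.88311
4	G24	1123	-0.12178
4	G25	1133	633.07361
4	G26	1222	-0.07104
4	G27	1223	0.07556
4	G28	1233	0.02058
4	G29	1333	0.23205
4	G30	2222	1898.67454
4	G31	2223	-0.34235
4	G32	2233	633.0568
4	G33	2333	-0.31836
4	G34	3333	1899.746
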