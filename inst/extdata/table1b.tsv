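field	year	month	role	delta15n	sd	letter
1	2011	NA	reference	5.86	0.61	a
1	2011	2	fixer	4.57	1.39	ab
1	2011	3	fixer	2.36	0.67	b
1	2011	4	fixer	3.92	0.30	b
1	2011	5	fixer	4.04	0.36	b
1	2011	6	fixer	3.39	0.20	b
1	2012	NA	reference	4.14	0.35	a
1	2012	2	fixer	6.38	1.09	a
1	2012	3	fixer	0.78	1.26	c
1	2012	4	fixer	3.27	1.98	b
1	2012	5	fixer	3.77	0.33	b
1	2012	6	fixer	2.66	0.22	b
2	2011	NA	reference	5.19	0.64	a
2	2011	2	fixer	4.86	1.39	a
2	2011	3	fixer	2.10	0.74	bc
2	2011	4	fixer	2.35	0.52	b
2	2011	5	fixer	1.20	0.22	c
2	2011	6	fixer	2.74	0.41	b
2	2012	NA	reference	2.72	0.26	a
2	2012	2	fixer	-1.02	0.90	bc
2	2012	3	fixer	-2.73	1.07	c
2	2012	4	fixer	-0.61	0.23	b
2	2012	5	fixer	0.37	0.31	b
2	2012	6	fixer	-0.41	0.20	b
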