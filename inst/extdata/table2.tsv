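field	year	stage	variety	role	atom15n_excess	ndfa	shootn	ndiff	atom_sig	shootn_sig
3	2016	V9	Reference	reference	0.60	NA	5.1	NA	FALSE	FALSE
3	2016	V9	SM1	fixer	0.35	43.5	11.1	46.4	FALSE	TRUE
3	2016	V9	SM2	fixer	0.57	10.3	6.6	22.0	FALSE	FALSE
3	2016	V12	Reference	reference	0.28	NA	21.3	NA	FALSE	FALSE
3	2016	V12	SM1	fixer	0.19	30.2	31.7	29.1	FALSE	FALSE
3	2016	V12	SM2	fixer	0.24	14.9	27.5	23.3	FALSE	FALSE
3	2016	Tassel	Reference	reference	0.21	NA	12.0	NA	FALSE	FALSE
3	2016	Tassel	SM1	fixer	0.18	21.5	27.3	46.5	FALSE	FALSE
3	2016	Tassel	SM2	fixer	0.15	29.0	34.2	60.6	TRUE	TRUE
3	2017	Tassel	Reference	reference	0.24	NA	5.9	NA	FALSE	FALSE
3	2017	Tassel	SM2	fixer	0.23	5.0	24.2	75.0	FALSE	TRUE
4	2016	V9	Reference	reference	0.16	NA	21.8	NA	FALSE	FALSE
4	2016	V9	SM1	fixer	0.17	5.6	31.5	28.5	FALSE	TRUE
4	2016	V9	SM2	fixer	0.10	33.4	19.9	1.9	FALSE	FALSE
4	2016	V12	Reference	reference	0.12	NA	58.5	NA	FALSE	FALSE
4	2016	V12	SM1	fixer	0.07	32.9	84.5	29.2	FALSE	FALSE
4	2016	V12	SM2	fixer	0.08	30.4	94.6	30.1	FALSE	FALSE
4	2016	Tassel	Reference	reference	0.09	NA	58.2	NA	FALSE	FALSE
4	2016	Tassel	SM1	fixer	0.05	48.1	122.3	48.7	TRUE	TRUE
4	2016	Tassel	SM2	fixer	0.05	43.2	101.8	37.6	TRUE	FALSE
4	2017	Tassel	Reference	reference	0.21	NA	28.5	NA	FALSE	FALSE
4	2017	Tassel	SM1	fixer	0.17	15.0	30.2	13.0	FALSE	FALSE
4	2017	Tassel	SM2	fixer	0.19	6.0	51.3	46.0	FALSE	TRUE
5	2016	V9	Reference	reference	0.45	NA	6.2	NA	FALSE	FALSE
5	2016	V9	SM1	fixer	0.23	48.5	14.9	56.8	TRUE	TRUE
5	2016	V9	SM2	fixer	0.24	46.4	10.5	37.9	TRUE	FALSE
5	2016	V12	Reference	reference	0.23	NA	16.4	NA	FALSE	FALSE
5	2016	V12	SM1	fixer	0.16	33.3	46.2	61.1	FALSE	TRUE
5	2016	V12	SM2	fixer	0.12	48.0	37.2	52.7	TRUE	TRUE
5	2016	Tassel	Reference	reference	0.18	NA	9.8	NA	FALSE	FALSE
5	2016	Tassel	SM1	fixer	0.08	55.3	61.4	82.2	TRUE	TRUE
5	2016	Tassel	SM2	fixer	0.08	55.1	43.1	76.6	TRUE	TRUE
5	2017	Tassel	Reference	reference	0.41	NA	8.4	NA	FALSE	FALSE
5	2017	Tassel	SM1	fixer	0.27	32.0	30.5	70.0	TRUE	TRUE
5	2017	Tassel	SM2	fixer	0.27	33.0	27.0	71.0	TRUE	TRUE
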