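sample	role	field	level	delta15n	sd	letter
Rumex obtusifolius	reference	NA	species	5.88	0.44	NA
Ipomoea purpurea	reference	NA	species	4.55	0.29	NA
Bougainvillea sp.	reference	NA	species	6.31	0.49	NA
Sambucus canadensis	reference	NA	species	6.76	0.09	NA
Hymenocallis chiapasiana	reference	NA	species	4.08	0.16	NA
Physalis philadelphica	reference	NA	species	6.12	0.18	NA
Ipomoea purpurea (2)	reference	NA	species	5.53	0.20	NA
Melampodium perfoliatum	reference	NA	species	4.29	0.09	NA
Reference plants mean	reference	NA	group_mean	5.42	0.21	a
Maiz Blanco Conasupo mean	conventional	NA	group_mean	4.87	0.57	a
Z. mays S. Mixe Field 1	fixer	1	field_mean	3.05	0.82	NA
Z. mays S. Mixe Field 2	fixer	2	field_mean	2.36	0.94	NA
Z. mays S. Mixe mean	fixer	NA	group_mean	2.71	0.60	b
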