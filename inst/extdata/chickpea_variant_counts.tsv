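cohort	n_genotypes	snp_exon	snp_intron	snp_intergenic	snp_total	indel_exon	indel_intron	indel_intergenic	indel_total	cnv	pav
all	129	46387	115360	1217043	1378790	1229	17222	132989	151440	3822	24603
market_all	129	46387	115360	1217043	1378790	1229	17222	132989	151440	3822	24603
desi	88	44859	110908	1167349	1323116	1154	16399	126493	144046	2954	23160
kabuli	41	38964	94971	1016430	1150365	808	11482	90746	103036	3273	21706
yearwise_all	124	46309	115007	1212774	1374090	1211	17107	131928	150246	3811	24249
RP1	38	39789	97459	1035388	1172636	984	14476	108089	123549	2315	20734
RP2	40	40380	99195	1055415	1194990	810	11412	91292	103514	2318	21150
RP3	46	42210	104952	1095817	1242979	861	12386	99123	112370	3511	22045
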