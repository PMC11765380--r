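species	group	pcg	nps1	nps2	nps3	per_pcg_1_printed	per_pcg_2_printed	per_pcg_3_printed
Escherichia coli	Bacteria	6066	7238	7368	37528	1.2	1.2	6.2
Staphylococcus aureus	Bacteria	10245	11254	11254	59712	1.1	1.1	5.8
Podospora anserina	Fungi	100	102	102	202	1	1	2
Saccharomyces cerevisiae	Fungi	6727	14794	16572	100972	2.2	2.5	15
Schizosaccharomyces pombe	Fungi	5201	7934	8188	37196	1.5	1.6	7.2
Apis mellifera	Animal	99	172	193	842	1.7	1.9	8.5
Caenorhabditis elegans	Animal	4484	7914	22490	69332	1.8	5	15.5
Callithrix jacchus	Animal	110	494	625	2072	4.5	5.7	18.8
Canis lupus familiaris	Animal	848	3510	4276	12307	4.1	5	14.5
Cavia porcellus	Animal	306	931	1185	3272	3	3.9	10.7
Chlorocebus aethiops	Animal	128	558	709	2578	4.4	5.5	20.1
Danio rerio	Animal	3338	4483	7067	32953	1.3	2.1	9.9
Drosophila melanogaster	Animal	3796	12844	35464	151871	3.4	9.3	40
Equus caballus	Animal	292	1159	1302	5962	4	4.5	20.4
Gallus gallus	Animal	2309	4229	7058	33259	1.8	3.1	14.4
Heterocephalus glaber	Animal	6	13	13	13	2.2	2.2	2.2
Macaca mulatta	Animal	365	1374	1851	9108	3.8	5.1	25
Homo sapiens	Animal	20429	228613	722907	3245524	11.2	35.4	158.9
Mus musculus	Animal	17775	82775	202478	749909	4.7	11.4	42.2
Oryctolagus cuniculus	Animal	978	4381	5598	19569	4.5	5.7	20
Ovis aries	Animal	467	1620	1927	8340	3.5	4.1	17.9
Rattus norvegicus	Animal	8202	38059	60773	217124	4.6	7.4	26.5
Sus scrofa	Animal	1459	6486	7600	27664	4.4	5.2	19
Xenopus laevis	Animal	3507	4814	6734	47145	1.4	1.9	13.4
Arabidopsis thaliana	Plant	16431	29015	76736	395227	1.8	4.7	24.1
Oryza sativa	Plant	4190	5256	7902	28387	1.3	1.9	6.8
Panax ginseng	Plant	135	150	159	159	1.1	1.2	1.2
Pinus koraiensis	Plant	71	82	82	82	1.2	1.2	1.2
Triticum aestivum	Plant	381	505	505	3267	1.3	1.3	8.6
Zea mays	Plant	853	1152	1560	12859	1.4	1.8	15.1
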