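species	taxon_id	genes_ensembl	pcg_swissprot	percent_printed	group	redundant
Staphylococcus aureus	1280	6220	10245	164	Bacteria	TRUE
Escherichia coli (strain K12)	83333	5079	6066	119	Bacteria	TRUE
Homo sapiens	9606	19846	20429	103	Animal	TRUE
Saccharomyces cerevisiae	559292	6600	6727	101	Fungi	TRUE
Schizosaccharomyces pombe	284812	5145	5201	101	Fungi	TRUE
Pinus koraiensis	88728	71	71	100	Plant	FALSE
Mus musculus	10090	21700	17228	82	Animal	FALSE
Arabidopsis thaliana	3702	27655	16389	59	Plant	FALSE
Rattus norvegicus	10116	24964	8205	32	Animal	FALSE
Drosophila melanogaster	7227	13986	3796	27	Animal	FALSE
Caenorhabditis elegans	6239	19985	4487	22	Animal	FALSE
Gallus gallus	9031	17077	2309	13	Animal	FALSE
Oryza sativa subsp. japonica	39947	35804	4190	11	Plant	FALSE
Danio rerio	7955	30153	3343	11	Animal	FALSE
Sus scrofa	9823	22040	1459	6.6	Animal	FALSE
Oryctolagus cuniculus	9986	20599	978	4.7	Animal	FALSE
Canis lupus familiaris	9615	20974	854	4	Animal	FALSE
Xenopus laevis	8355	108155	3507	3.2	Animal	FALSE
Panax ginseng	4054	6050	135	2.2	Plant	FALSE
Zea mays	4577	39756	853	2.1	Plant	FALSE
Ovis aries	9940	21890	467	2.1	Animal	FALSE
Cavia porcellus	10141	18095	306	1.6	Animal	FALSE
Macaca mulatta	9544	21591	365	1.6	Animal	FALSE
Equus caballus	9796	21426	292	1.3	Animal	FALSE
Apis mellifera	7460	9935	99	1	Animal	FALSE
Podospora anserina	515849	10544	100	0.9	Fungi	FALSE
Chlorocebus aethiops	9534	19165	128	0.6	Animal	FALSE
Callithrix jacchus	9483	21965	110	0.5	Animal	FALSE
Triticum aestivum	4565	145065	381	0.2	Plant	FALSE
Heterocephalus glaber	10181	23320	6	0.03	Animal	FALSE
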