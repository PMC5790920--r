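taxon_id	parent_id	rank	name
1	NA	domain	d__Bacteria
2	1	phylum	p__Actinobacteria
3	1	phylum	p__Proteobacteria
4	1	phylum	p__Firmicutes
5	1	phylum	p__Bacteroidetes
6	1	phylum	p__Chloroflexi
10	2	class	c__Actinobacteria
11	10	order	o__Corynebacteriales
12	10	order	o__Propionibacteriales
13	11	family	f__Nocardiaceae
14	11	family	f__Mycobacteriaceae
15	12	family	f__Nocardioidaceae
16	13	genus	g__Rhodococcus
17	13	genus	g__Gordonia
18	14	genus	g__Mycobacterium
19	15	genus	g__Nocardioides
20	3	class	c__Alphaproteobacteria
21	20	order	o__Sphingomonadales
22	20	order	o__Rhodobacterales
23	20	order	o__Rhizobiales
24	21	family	f__Sphingomonadaceae
25	22	family	f__Rhodobacteraceae
26	22	family	f__Hyphomonadaceae
27	24	genus	g__Sphingomonas
28	24	genus	g__Novosphingobium
29	26	genus	g__Hellea
30	3	class	c__Betaproteobacteria
31	30	order	o__Burkholderiales
32	30	order	o__Rhodocyclales
33	31	family	f__Comamonadaceae
34	32	family	f__Rhodocyclaceae
35	33	genus	g__Comamonas
36	34	genus	g__Thauera
40	3	class	c__Gammaproteobacteria
41	40	order	o__Pseudomonadales
42	40	order	o__Oceanospirillales
43	40	order	o__Alteromonadales
44	40	order	o__Cellvibrionales
45	41	family	f__Pseudomonadaceae
46	42	family	f__Oceanospirillaceae
47	43	family	f__Alteromonadaceae
48	43	family	f__Colwelliaceae
49	43	family	f__Pseudoalteromonadaceae
50	44	family	f__Spongiibacteraceae
51	44	family	f__Halieaceae
52	45	genus	g__Pseudomonas
53	46	genus	g__Marinobacterium
54	48	genus	g__Colwellia
55	49	genus	g__Pseudoalteromonas
56	50	genus	g__Spongiibacter
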