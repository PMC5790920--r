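sponge	sponge_accession	isolate_id	silva_best_hit	taxonomy	genbank_accession
Suberitidae	SAMN02192789	BC51	97.0	Gammaproteobacteria; Cellvibrionales; Halieaceae	MF770252
Suberitidae	SAMN02192789	BC52	92.8	Gammaproteobacteria; Cellvibrionales; Spongiibacteraceae; BD1-7 clade	MF770253
Geodia	SAMN02192792	BC81	97.8	Actinobacteria; Corynebacteriales; Mycobacteriaceae; Mycobacterium	MF770254
Hymeniacidon	SAMN02192793	BC91	92.7	Gammaproteobacteria; Cellvibrionales; Spongiibacteraceae; BD1-7 clade	MF770255
Hymeniacidon	SAMN02192793	BC92	99.5	Gammaproteobacteria; Alteromonadales; Colwelliaceae; Colwellia	MF770256
Tethya	SAMN02192796	SB113	93.1	Gammaproteobacteria; Cellvibrionales; Spongiibacteraceae; BD1-7 clade	MF770257
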