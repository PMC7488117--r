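rsID	Chromosome	Position (GRCh38)	BeadChip genotype	WGS genotype	Sanger genotype
rs12731384	1	109711898	TG	GG	TT
rs1633365	1	109711919	TC	TT	TC
rs58877308	1	109712113	CG	GG	GG
rs138687644	1	109759369	GG	GG	G-
rs202018423	1	109759339	CC	CC	CC
rs757293027	1	109759384	CC	CC	C-
rs760279355	1	109759346	CC	CC	CC
rs767809812	1	109759359	DD	II	I-
rs79394341	1	109759361	GG	GG	G-
rs786205634	2	85663647	DI	II	II
rs3832043	2	233671807	II	DI	DD
rs144484152	6	160246683	GG	AA	AA
rs149262397	6	160246574	CC	CC	CC
rs316022	6	160246568	GG	AA	AA
rs529525717	6	160246473	GG	GG	GG
rs537568133	6	160246590	TT	CC	CC
rs549969754	6	160246607	CC	CC	CC
rs555024471	6	160246297	GG	GG	G-
rs563560445	6	160246467	CC	CC	CC
rs563829592	6	160246443	GG	GG	G-
rs577352795	6	160246460	TT	TT	T-
rs757852385	6	160246688	AA	AA	AA
rs759566284	6	160246458	GG	GG	G-
rs200896335	10	101010536	DD	II	NA
rs753420953	13	49792587	DD	DI	NA
rs397515367	22	37973817	DD	II	II
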