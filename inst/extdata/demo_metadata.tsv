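sequence_id	specimen_id	species	locus
its_sp01_1	sp01_1	Boletus demo-A	ITS
its_sp01_2	sp01_2	Boletus demo-A	ITS
its_sp02_1	sp02_1	Boletus demo-B	ITS
its_sp02_2	sp02_2	Boletus demo-B	ITS
coi_sp01_1	sp01_1	Boletus demo-A	COI
coi_sp01_2	sp01_2	Boletus demo-A	COI
coi_sp02_1	sp02_1	Boletus demo-B	COI
coi_sp02_2	sp02_2	Boletus demo-B	COI
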