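!gaf-version: 2.1
!synthetic 10-entity annotation fixture over toy_similarity.obo
DB	P01	p01	 	B:0001	REF:1	IDA	 	P	protein 1	 	protein	taxon:0	20260101	DB
DB	P02	p02	 	B:0001	REF:1	IDA	 	P	protein 2	 	protein	taxon:0	20260101	DB
DB	P03	p03	 	B:0002	REF:1	IDA	 	P	protein 3	 	protein	taxon:0	20260101	DB
DB	P04	p04	 	B:0002	REF:1	IDA	 	P	protein 4	 	protein	taxon:0	20260101	DB
DB	P05	p05	 	B:0001	REF:1	IDA	 	P	protein 5	 	protein	taxon:0	20260101	DB
DB	P05	p05	 	B:0003	REF:1	IDA	 	P	protein 5	 	protein	taxon:0	20260101	DB
DB	P06	p06	 	B:0003	REF:1	IDA	 	P	protein 6	 	protein	taxon:0	20260101	DB
DB	P07	p07	 	B:0004	REF:1	IDA	 	P	protein 7	 	protein	taxon:0	20260101	DB
DB	P08	p08	 	B:0004	REF:1	IDA	 	P	protein 8	 	protein	taxon:0	20260101	DB
DB	P09	p09	 	B:0003	REF:1	IDA	 	P	protein 9	 	protein	taxon:0	20260101	DB
DB	P09	p09	 	B:0004	REF:1	IDA	 	P	protein 9	 	protein	taxon:0	20260101	DB
DB	P10	p10	 	B:0002	REF:1	IDA	 	P	protein 10	 	protein	taxon:0	20260101	DB
DB	P10	p10	 	B:0004	REF:1	IDA	 	P	protein 10	 	protein	taxon:0	20260101	DB
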