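# Synthetic example of a per-genome domain annotation file (tab-separated:
# genome id, protein/sequence id, region start-end, superfamily id).
# Hand-written for examples and documentation; not derived from any database.
hs	SRC_HUMAN	84-140	50044
hs	SRC_HUMAN	148-235	55550
hs	SRC_HUMAN	270-520	56112
hs	ZNF_EXAMPLE	10-35	57667
hs	ZNF_EXAMPLE	40-65	57667
hs	ZNF_EXAMPLE	70-95	57667
hs	IG_EXAMPLE	25-110	48726
hs	IG_EXAMPLE	120-205	48726
hs	KIN_ONLY	12-270	56112
mm	SRC_MOUSE	82-138	50044
mm	SRC_MOUSE	146-233	55550
mm	SRC_MOUSE	268-518	56112
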