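category	15DAF	36DAF	81DAF	110DAF	145DAF	167DAF
total_reads	22354861	23934357	19030925	25576773	23934213	24527030
clean_reads	21612084	23153525	18618514	25086346	23575395	24263969
exon_antisense	319460	308465	218280	257309	215078	220482
exon_sense	509150	453742	341272	398473	365311	350102
intron_antisense	377104	395221	298440	378094	331083	360635
intron_sense	797178	619168	528500	614109	662064	599612
known_mirna	1147166	1014459	1271600	1590575	1170540	1113401
rrna_etc	1158744	756242	617356	708315	607519	635925
repeat	9514359	10881244	8544263	11564973	11161868	11351321
unannotated	7788923	8724984	6798803	9574498	9061932	9632491
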