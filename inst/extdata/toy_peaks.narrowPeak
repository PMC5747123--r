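chr1	100	200	pk1	0	+	8	4	-1	-1
chr1	300	420	pk2	0	+	7.9	10	-1	-1
chr1	500	600	pk3	0	-	12	3.9	-1	-1
chr2	100	250	pk4	0	+	9.5	5	-1	-1
chr2	400	500	pk5	0	-	8	4	-1	-1
chr3	50	150	pk6	0	+	20	8	-1	-1
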