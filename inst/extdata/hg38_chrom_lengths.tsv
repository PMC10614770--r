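chr1	248956422	2
chr2	242193529	2
chr3	198295559	2
chr4	190214555	2
chr5	181538259	2
chr6	170805979	2
chr7	159345973	2
chr8	145138636	2
chr9	138394717	2
chr10	133797422	2
chr11	135086622	2
chr12	133275309	2
chr13	114364328	2
chr14	107043718	2
chr15	101991189	2
chr16	90338345	2
chr17	83257441	2
chr18	80373285	2
chr19	58617616	2
chr20	64444167	2
chr21	46709983	2
chr22	50818468	2
chrX	156040895	1
chrY	57227415	1
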