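species	total	protein	protein_nonsyn	rrna	trna
Haemaphysalis formosensis	6	6	1	0	0
Haemaphysalis parva	6	5	4	0	1
Rhipicephalus microplus	40	34	3	0	6
Amblyomma cajennense	166	136	33	22	8
Argas sp.	11	10	0	1	0
Rhipicephalus geigyi	8	7	5	0	1
Otobius megnini	24	23	17	1	0
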