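sample_a	sample_b	shared
B2470B1	B2471H5	0
B2470B1	B2557B	0
B2470B1	B2557H	0
B2470B1	B2558B	0
B2470B1	B2558H	2
B2470B1	B2516B2	5
B2470B1	B2516H2	1
B2470B1	B2560B	0
B2470B1	B2560H	0
B2470B1	B2563B2	1
B2470B1	B2563H	6
B2471H5	B2557B	0
B2471H5	B2557H	2
B2471H5	B2558B	1
B2471H5	B2558H	3
B2471H5	B2516B2	5
B2471H5	B2516H2	2
B2471H5	B2560B	0
B2471H5	B2560H	0
B2471H5	B2563B2	2
B2471H5	B2563H	6
B2557B	B2557H	3
B2557B	B2558B	0
B2557B	B2558H	5
B2557B	B2516B2	3
B2557B	B2516H2	0
B2557B	B2560B	1
B2557B	B2560H	0
B2557B	B2563B2	2
B2557B	B2563H	11
B2557H	B2558B	3
B2557H	B2558H	5
B2557H	B2516B2	4
B2557H	B2516H2	0
B2557H	B2560B	1
B2557H	B2560H	0
B2557H	B2563B2	3
B2557H	B2563H	7
B2558B	B2558H	2
B2558B	B2516B2	2
B2558B	B2516H2	0
B2558B	B2560B	0
B2558B	B2560H	0
B2558B	B2563B2	1
B2558B	B2563H	10
B2558H	B2516B2	3
B2558H	B2516H2	0
B2558H	B2560B	0
B2558H	B2560H	0
B2558H	B2563B2	2
B2558H	B2563H	9
B2516B2	B2516H2	13
B2516B2	B2560B	11
B2516B2	B2560H	14
B2516B2	B2563B2	55
B2516B2	B2563H	0
B2516H2	B2560B	0
B2516H2	B2560H	21
B2516H2	B2563B2	1
B2516H2	B2563H	1
B2560B	B2560H	0
B2560B	B2563B2	0
B2560B	B2563H	2
B2560H	B2563B2	1
B2560H	B2563H	1
B2563B2	B2563H	2
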