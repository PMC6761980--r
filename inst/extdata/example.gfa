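H	VN:Z:1.0
S	ref1	ACGTTGCA
S	altA	A
S	refC	C
S	ref2	GGATC
S	ref3	TTACGGA
L	ref1	+	altA	+	0M
L	ref1	+	refC	+	0M
L	altA	+	ref2	+	0M
L	refC	+	ref2	+	0M
L	ref2	+	ref3	+	0M
L	ref2	+	ref2	+	0M
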