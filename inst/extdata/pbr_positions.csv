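codon
9
25
27
34
35
44
53
57
58
62
65
67
68
71
75
78
79
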