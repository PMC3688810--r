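# Antigen-binding-site (peptide-binding) codons of the MHC class II beta-1
# domain, from the human DRB1 crystal structure (Brown et al. 1993),
# 1-based positions on the mature beta-1 domain. Map onto a specific
# exon-2 alignment via the offset argument of defaultAbsMask().
9
11
13
26
28
30
32
37
38
47
56
57
60
61
65
68
70
71
74
78
81
82
85
86
88
89
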