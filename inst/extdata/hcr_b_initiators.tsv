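# HCR v3 B-series amplifier initiators (B1-B5), 36 nt each, split into the
# two 18-nt halves carried by a split-probe pair, with the default flexible
# connector dinucleotides. Sequences follow the published third-generation
# HCR amplifier definitions (Choi et al. 2018, Development 145, dev165753)
# as used by public split-initiator probe generators. Replace this file (or
# pass your own via load_initiators(path=...)) to use vendor-issued or
# custom initiators.
id	full_seq	half_up	half_dn	conn_up	conn_dn
B1	GAGGAGGGCAGCAAACGGGAAGAGTCTTCCTTTACG	GAGGAGGGCAGCAAACGG	GAAGAGTCTTCCTTTACG	AA	TT
B2	CCTCGTAAATCCTCATCAATCATCCAGTAAACCGCC	CCTCGTAAATCCTCATCA	ATCATCCAGTAAACCGCC	AA	TT
B3	GTCCCTGCCTCTATATCTCCACTCAACTTTAACCCG	GTCCCTGCCTCTATATCT	CCACTCAACTTTAACCCG	AA	TT
B4	CCTCAACCTACCTCCAACTCTCACCATATTCGCTTC	CCTCAACCTACCTCCAAC	TCTCACCATATTCGCTTC	AA	TT
B5	CTCACTCCCAATCTCTATCTACCCTACAAATCCAAT	CTCACTCCCAATCTCTAT	CTACCCTACAAATCCAAT	AA	TT
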