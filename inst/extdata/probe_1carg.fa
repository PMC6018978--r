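>probe_1carg 51-nt saturation-assay probe, single central CArG-box; letters as printed, interpreted as the 5'->3' sense strand (the source's 3'/5' end labels are inconsistent with the shared CArG cassette of the 151-nt probe)
AATTCGAAATTTAATTATATTCCAAATAAGGAAAGTATGGAACGTTGAATT
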