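>SEP3_synthetic synthetic SEP3-like reference (NOT the natural sequence); carries the documented residues S94, L101, V104, L108, I111, L115, L120, L123, L128, L131, L135, L145, M150, L154, L157, E161, L164, N168, L171, G178 at their published full-protein coordinates
LQAEIQAAEQGDTEAGRKAAMARTVNNNQTSQQQTNLRRQMNEKLGAEVKEKKRGRENQA
ISSQESASNQRGASEKIAGRQSKANRTEGQEGMSAEMGQQLKNVVSELAQIALELKDQEL
ADLKQSSLTALDGALTLTANNESDLEREKMASLLRGLETNESQLITKNADLALADADGNK
MDQTL
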