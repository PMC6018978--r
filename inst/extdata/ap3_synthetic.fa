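>AP3_synthetic synthetic AP3-like donor (NOT the natural sequence); coordinates aligned to the SEP3-like reference, with T157 and Q164 at the tetramerization-interface 'd' positions occupied by leucine in SEP3
IQRSLDTATTDDIREQKREEMGNGGRSQRGGGARDQSKKEISQTVSQSNQTRDKQANTGN
ATNNRGNSIREGRKRSSSTSADTGAESQSGRTSDGADQGNNATANDSENGDDEGTTQNKA
ASRNEEKGTRKAEQSDQKSQMSERIQDGMMSTMITETQSSEGNQARGSDTLDEKDTQGDT
NTNDD
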