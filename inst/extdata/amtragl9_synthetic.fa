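>AMtrAGL9_synthetic synthetic AMtrAGL9-like reference (NOT the natural sequence); carries I141 (homolog of SEP3 L145) and L160 (homolog of SEP3 L164) at their published coordinates
TRDDMNGQNGGGMRERMNSKLQTAGSGAMQKSMNEETNSDLREKQTQSAGESVDERESTN
SDNDRTNNTGNTISESISAGGKRRNTATMSGTMNKNLKDTNQDLSAQNLRLAANQLRSLN
ISGLQSLAAQLQNSKRRNGSISDQMMTRALKNLDTEEEQLLRDNAGNQNGSKSGRNLSKN
D
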