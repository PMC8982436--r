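>dme-miR-9a-5p
UCUUUGGUUAUCUAGCUGUAUGA
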