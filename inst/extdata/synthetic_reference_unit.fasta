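>synthetic_reference_unit synthetic consensus of a conserved first-array C2H2 zinc finger; anchors C8,C11,H24,H28; contact residues 13/16/19 = DSK
ACCGGAGAGAAGCCCTACGTGTGCAGAGAATGTGGCGATGAGCGGAGCGTCAGGAAACACCTGCGCATCCATCAGCGTACACAC
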