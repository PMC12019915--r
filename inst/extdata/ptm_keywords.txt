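# Supplementary PTM keyword list (UniProt keyword category "PTM"):
# umbrella keywords carried on KW lines that have no residue-level
# entry in the controlled vocabulary.
Phosphoprotein
Glycoprotein
Acetylation
Methylation
Lipoprotein
Ubl conjugation
Disulfide bond
Isopeptide bond
GPI-anchor
Hydroxylation
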