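protein,category
P0001,Collagens
P0002,ECM Glycoproteins
P0003,ECM Glycoproteins
P0004,Proteoglycans
P0005,ECM Regulators
P0006,Secreted Factors
P0007,ECM-affiliated Proteins
P0008,Collagens
P0010,ECM Regulators
P0012,ECM Glycoproteins
COL1A1,Collagens
COL3A1,Collagens
FN1,ECM Glycoproteins
SPARC,ECM Glycoproteins
IGFBP5,ECM Regulators
GAS6,Secreted Factors
VCAN,Proteoglycans
ANXA2,ECM-affiliated Proteins
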