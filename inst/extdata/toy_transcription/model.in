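# Toy transcription model: one polymerase species cycling over a short
# template read from an accompanying FASTA file.

FreeChemical RNAP
FreeChemical ATP buffered
FreeChemical UTP buffered
FreeChemical GTP buffered
FreeChemical CTP buffered
FreeChemical PPi

BoundChemical P_loading
BoundChemical P_loaded
BoundChemical P_ready
BoundChemical P_term

Sequence dna fasta template.fa tmpl1
Sequence rna fasta template.fa tmpl1

BindingSite prom dna 0 4 0.1 0.5 0
SequenceBinding bind RNAP P_loading prom

Loading load P_loading
T ATP 0.001 P_loaded PPi
A UTP 0.001 P_loaded PPi
C GTP 0.001 P_loaded PPi
G CTP 0.001 P_loaded PPi

ChemicalReaction polymerize 500 0 : 1 P_loaded -> 1 P_ready
Translocation step P_ready P_loading 1 50

Switch term_switch P_loading P_term
SwitchSite dna 19 term_switch

Release terminate P_term 1 RNAP
prom 19 20 rna

Init RNAP 3
Init dna 1
Init ATP 600000
Init UTP 600000
Init GTP 600000
Init CTP 600000

Observe rna RNAP PPi
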