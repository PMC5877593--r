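gene	annotation
PDGFRA	kinase inhibitor sensitivity/resistance by mutation subtype
TP53	biallelic inactivation; not directly targetable
IDH1	IDH inhibitors for hotspot gain-of-function mutations
FBXW7	resistance marker for selected targeted agents
SDHB	SDH-deficiency workup; germline counselling
KIT	kinase inhibitor sensitivity by exon
BRAF	RAF/MEK inhibitors for V600 class
EGFR	EGFR TKIs for activating mutations
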