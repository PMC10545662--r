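# SYNTHETIC knowledge-base snapshot: gene / protein positions with a known pathogenic
# missense variant (rule C of the triage screen matches on position only, not the alternate
# residue). See kb_pathogenic_variants.tsv for the assumption behind this assignment.
# GRIN2A 693 covers the novel p.(Asn693Asp); the remaining rows are decoys.
gene	position
GRIN2A	693
SCN1A	1783
MECP2	168
KCNQ2	213
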