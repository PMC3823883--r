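label	description	size	size_excluding_bait
WholeCellsNT-293T	HEK293T, not treated, whole cells	97	NA
MitoNT-293T	HEK293T, not treated, mitochondrial fraction	65	NA
CytoNT-293T	HEK293T, not treated, cytosolic fraction	55	NA
MitoT-293T	HEK293T, treated, mitochondrial fraction	18	NA
CytoT-293T	HEK293T, treated, cytosolic fraction	22	NA
MitoT-SH-SY5Y	SH-SY5Y, treated, mitochondrial fraction	54	NA
CytoT-SH-SY5Y	SH-SY5Y, treated, cytosolic fraction	53	NA
ParkinTAP	union of all seven TAP datasets	203	NA
Mito	union of the three mitochondrial-fraction datasets	99	NA
Cyto	union of the three cytosolic-fraction datasets	94	NA
MonogenicPD	proteins of monogenic parkinsonism genes	9	NA
Pink1TAP	PINK1 TAP candidate interactors	17	NA
ParkinIP	known Parkin interactors in the interactome	77	NA
MonogenicPDIP	interactors of MonogenicPD proteins	668	NA
PINK1IP	known PINK1 interactors	44	NA
RelatedPD	union of ParkinIP and MonogenicPD	80	NA
overlap:Mito-Cyto	overlap between the fractions	49	NA
overlap:ParkinTAP-ParkinIP	candidates already known as bait interactors	4	3
overlap:ParkinTAP-MonogenicPD	candidates that are seed proteins	1	0
overlap:ParkinTAP-MonogenicPDIP	candidates interacting with a seed protein	40	39
overlap:ParkinTAP-Pink1TAP	candidates shared with the PINK1 TAP screen	15	15
overlap:ParkinIP-MonogenicPD	seed proteins that are bait interactors	6	5
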