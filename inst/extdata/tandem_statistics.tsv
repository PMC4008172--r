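species	total_nbs	tandem_genes	tandem_arrays	common_tandem_genes	common_tandem_arrays	on_chromosomes	unanchored
A.thaliana	167	93	37	20	10	93	0
B.rapa	206	97	40	14	7	93	4
B.oleracea	157	68	26	18	9	57	11
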