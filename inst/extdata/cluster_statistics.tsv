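species	genes_on_chromosomes	genes_in_clusters	clusters
B.oleracea	121	73	24
B.rapa	197	117	43
A.thaliana	167	103	37
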