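species	category	count
B.oleracea	TNL	40
B.oleracea	CNL	6
B.oleracea	NBS-LRR	24
B.oleracea	TIR-NBS	29
B.oleracea	CC-NBS	5
B.oleracea	NBS	53
B.oleracea	TIR-X	82
B.rapa	TNL	93
B.rapa	CNL	19
B.rapa	NBS-LRR	27
B.rapa	TIR-NBS	23
B.rapa	CC-NBS	15
B.rapa	NBS	29
B.rapa	TIR-X	42
A.thaliana	TNL	79
A.thaliana	CNL	17
A.thaliana	NBS-LRR	20
A.thaliana	TIR-NBS	17
A.thaliana	CC-NBS	8
A.thaliana	NBS	26
A.thaliana	TIR-X	46
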