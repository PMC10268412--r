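T1	Protein 0 5	PROT1
T2	Protein 17 22	PROT2
T3	Protein 51 56	PROT3
T4	Binding 6 13	binding
T5	Phosphorylation 32 47	phosphorylation
E1	Binding:T4 Theme:T1 Theme2:T2
E2	Phosphorylation:T5 Theme:T3
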