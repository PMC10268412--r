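# sent_id = ex1
1	PROT1	PROT1	NN	NN	_	2	nmod
2	binding	binding	NN	NN	_	5	nsubj
3	of	of	IN	IN	_	4	case
4	PROT2	PROT2	NN	NN	_	2	nmod
5	requires	require	VBZ	VBZ	_	0	root
6	phosphorylation	phosphorylation	NN	NN	_	5	dobj
7	of	of	IN	IN	_	8	case
8	PROT3	PROT3	NN	NN	_	6	nmod
9	.	.	.	.	_	5	punct
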