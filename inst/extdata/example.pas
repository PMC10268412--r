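ex1	5	2	arg1
ex1	5	6	arg2
ex1	2	1	arg1
ex1	2	4	arg2
ex1	6	8	arg2
ex1	3	4	arg1
ex1	7	8	arg1
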