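group	n_introns
IB	42
IA	17
ID	8
IC1	12
IC2	5
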