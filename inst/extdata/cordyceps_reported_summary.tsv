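species	genome_bp	n_introns	intron_bp
C_cicadae	51692	21	23347
C_militaris	29929	5	5306
C_cocoonihabita	45058	NA	NA
C_blackwelliae	42257	NA	NA
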