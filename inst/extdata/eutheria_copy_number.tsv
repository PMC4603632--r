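species	copies_a	copies_b	complete_genome
Dasypus_novemcinctus	0	1	FALSE
Homo_sapiens	1	1	TRUE
Pan_troglodytes	1	1	TRUE
Macaca_mulatta	1	1	TRUE
Cavia_porcellus	1	1	TRUE
Mus_musculus	2	2	TRUE
Rattus_norvegicus	2	2	TRUE
Bos_taurus	2	2	TRUE
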