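species_name,n_haplotypes,seq_length,sample_size
Picoides tridactylus,5,332,30
Pinicola enucleator,37,444,77
Calidris maritima,12,744,73
Carpodacus erythrinus,115,1038,190
Motacilla alba,57,906,209
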