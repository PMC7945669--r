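accession_id,sampled_frequency
SYN000001.1,50
SYN000002.1,7
SYN000003.1,3
SYN000004.1,1
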