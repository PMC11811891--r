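>TRR-TCT3-2_nontemplate human tRNA-Arg(TCT) gene, nontemplate strand, 98 nt
ACGTGTCTGGCTCTGTGGCGCAATGGATAGCGCATTGGACTTCTAGATAGTTAGAGAAAT
TCAAAGGTTGTGGGTTCGAGTCCCACAGAGTCGCTTTT
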