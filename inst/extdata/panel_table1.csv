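gene,accession,fwd,rev,amplicon_lo,amplicon_hi,genomic_bp
18S,AF173612,CGAAAGCATTTGCCAAGAAT,GGCATCGTTTATGGTCGG,98,99,98
ABL,XM_001233811,GCTGCTCGCTGGAACTCC,GTGATGTAATTGCTGGGGACC,218,218,940
GAPDH,NM_204305,GTGGTGCTAAGCGTGTTATCATC,GGCAGCACCTCTGCCATC,269,270,534
GUSB,NM_001039316,GGCAAACTCCTTCCGCAC,TCATTGGCTACTGACCACATCA,222,224,858
HMBS,XM_417846,CTGAAGAGAATGGGCTGGGA,TCTTGGTCTTTGGCACGAAC,113,115,1791
HPRT,NM_204848,GATGAACAAGGTTACGACCTGGA,TATAGCCACCCTTGAGTACACAGAG,181,181,1575
PGK1,NM_204985,AAAGTTCAGGATAAGATCCAGCTG,GCCATCAGGTCCTTGACAAT,167,167,450
RPL13,NM_204999,CCACAAGGACTGGCAGCG,ACGATGGGCCGGATGG,135,135,434
RPL19,NM_001030929,CCAACGAGACCAACGAGATC,CATGTGCCGGCCCTTCC,152,153,629
RPS7,XM_419936,TAGGTGGTGGCAGGAAAGC,TTGGCTTGGGCAGAATCC,156,156,1773
SDHA,XM_419054,TTGGTGGACAGAGTCTTCAGTT,GTGTTCTTTGCTCTAAAACGATG,238,238,1821
TFRC,NM_205256,GGAACTTGCCCGTGTGATC,GTAGCACCCACAGCTCCGT,111,113,723
VIM,NM_001048076,GGAACAATGATGCCCTGC,GCAAAATTCTCCTCCATTTCAC,145,145,761
YWHAZ,NM_001031343,GTGGAGCAATCACAACAGGC,GCGTGCGTCTTTGTATGACTC,222,224,326
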