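>exon2 SMIM45 exon 2 genomic sequence (1268 bp)
ccaaggccgccgcgatgccgcacttcctggactggttcgtgccggtctacttggtcatct
cggtcctcattctggtgggcttcggcgcctgcatctactacttcgagccgggcctgcagg
aggcgcacaagtggcgcatgcagcgccccctggtggaccgcgacctccgcaagacgctaa
tggtgcgcgacaacctggccttcggcggcccggaggtctgagccgacttgcaaaggggat
aggcgggcggcaccgggcgccctcccccagcccgccccgcccgcccagcccggagacccc
caaggcagagggaggccggcctgttggccctccacgctatccctctgcagcctgggccct
cccgacagaggccccaggtgcgctggcagtggaggtggggcacttaggtgcctggctggc
ccagggcttgctctccgtgtcaagccgactcacccagagcccaccctcccaagctcaggg
gcatcctccgctgggccccagtgcctttgcgctgcgcagcactctgccctccactggact
caggcatgtctatggctgcctgtcctgaggctccggagccctcatttcttcgtgaagtcc
ccagctcccctgcctccactcaatggcaccggccctgcaactttaggcaggtcgaagcca
acccaaggaaagaacctaagaacctcgtttggagggatgtcagcttgggccagaccagcc
gcaccccgcggggctcaggcttggaactggtgagggtgtgtggtgggggtatgcagaggg
ataagaccgtggtagaggagagggttggtgaggagagagagagagagagagagagagtct
ggggggagcgggcaagcatggggagatgagatgtgtatatgtgagagagagtgtgggggc
cccaggcagggcaggaggtggtggaaacggggtgaactccgtgggctgtgtgaggactgt
ccatagtgggtcccaaccccctccctctgctggagtttcctagcccttccccctccccaa
gactgtggcagcaggcaggagcccctgccctccctccctgtcctgtgccacacttctggg
gccaaacccagcccccttgagccaggccctgccagactccaagcccaccctagaaccctc
ctcctgtgtggagactctgttgccccactttggacacagattggcaacctgcctcacccc
gccccccttcgctggggcttccatcttaatttattctcaataataaagacttcatgatga
tctctgca
>mrna68 deduced mRNA of the 68 aa ORF (207 nt)
atgccgcacttcctggactggttcgtgccggtctacttggtcatctcggtcctcattctg
gtgggcttcggcgcctgcatctactacttcgagccgggcctgcaggaggcgcacaagtgg
cgcatgcagcgccccctggtggaccgcgacctccgcaagacgctaatggtgcgcgacaac
ctggccttcggcggcccggaggtctga
>mrna107 deduced mRNA of the 107 aa ORF (324 nt)
atgtctatggctgcctgtcctgaggctccggagccctcatttcttcgtgaagtccccagc
tcccctgcctccactcaatggcaccggccctgcaactttaggcaggtcgaagccaaccca
aggaaagaacctaagaacctcgtttggagggatgtcagcttgggccagcccagccgcacc
ccgcggggctcaggcttggaactggtgagggtgtgtggtgggggtatgcagagggataag
accgtggtagaggagagggttggtgaggagagagagagagagagagagagagtctggggg
gagcgggcaagcatggggagatga
>intervening intervening sequence between the 68 aa and 107 aa regions (324 nt)
gccgacttgcaaaggggataggcgggcggcaccgggcgccctcccccagcccgccccgcc
cgcccagcccggagacccccaaggcagagggaggccggcctgttggccctccacgctatc
cctctgcagcctgggccctcccgacagaggccccaggtgcgctggcagtggaggtggggc
acttaggtgcctggctggcccagggcttgctctccgtgtcaagccgactcacccagagcc
caccctcccaagctcaggggcatcctccgctgggccccagtgcctttgcgctgcgcagca
ctctgccctccactggactcaggc
>silencer transcriptional silencer LOC130067579 (230 nt)
tgcgcgacaacctggccttcggcggcccggaggtctgagccgacttgcaaaggggatagg
cgggcggcaccgggcgccctcccccagcccgccccgcccgcccagcccggagacccccaa
ggcagagggaggccggcctgttggccctccacgctatccctctgcagcctgggccctccc
gacagaggccccaggtgcgctggcagtggaggtggggcacttaggtgcct
>transcript_v1 SMIM45 transcript variant 1, NM_001395940.1 (1540 nt)
ctctgatgggcagggagagataccagggtgctgagccagtccaggactgccccctcctgg
cccactcagagcccctgggtgtgagaagctcgtctcccgtgggttgcattggctctgccc
tatctctgcctccagcacccagggcggccgcagatggcagtgtctctggggacagcagct
gcgaatgagtccacgggccaatgctgagctgctcaggctgaggcggtgtgctcagcacag
agcccccggaactggcatctgcagggcgtgagccaaggccgccgcgatgccgcacttcct
ggactggttcgtgccggtctacttggtcatctcggtcctcattctggtgggcttcggcgc
ctgcatctactacttcgagccgggcctgcaggaggcgcacaagtggcgcatgcagcgccc
cctggtggaccgcgacctccgcaagacgctaatggtgcgcgacaacctggccttcggcgg
cccggaggtctgagccgacttgcaaaggggataggcgggcggcaccgggcgccctccccc
agcccgccccgcccgcccagcccggagacccccaaggcagagggaggccggcctgttggc
cctccacgctatccctctgcagcctgggccctcccgacagaggccccaggtgcgctggca
gtggaggtggggcacttaggtgcctggctggcccagggcttgctctccgtgtcaagccga
ctcacccagagcccaccctcccaagctcaggggcatcctccgctgggccccagtgccttt
gcgctgcgcagcactctgccctccactggactcaggcatgtctatggctgcctgtcctga
ggctccggagccctcatttcttcgtgaagtccccagctcccctgcctccactcaatggca
ccggccctgcaactttaggcaggtcgaagccaacccaaggaaagaacctaagaacctcgt
ttggagggatgtcagcttgggccagaccagccgcaccccgcggggctcaggcttggaact
ggtgagggtgtgtggtgggggtatgcagagggataagaccgtggtagaggagagggttgg
tgaggagagagagagagagagagagagagtctggggggagcgggcaagcatggggagatg
agatgtgtatatgtgagagagagtgtgggggccccaggcagggcaggaggtggtggaaac
ggggtgaactccgtgggctgtgtgaggactgtccatagtgggtcccaaccccctccctct
gctggagtttcctagcccttccccctccccaagactgtggcagcaggcaggagcccctgc
cctccctccctgtcctgtgccacacttctggggccaaacccagcccccttgagccaggcc
ctgccagactccaagcccaccctagaaccctcctcctgtgtggagactctgttgccccac
tttggacacagattggcaacctgcctcaccccgccccccttcgctggggcttccatctta
atttattctcaataataaagacttcatgatgatctctgca
>devseq_rna RNA encoding the early developmental peptide SGLELVRVCGGGMQRDKT (54 nt)
tcaggcttggaactggtgagggtgtgtggtgggggtatgcagagggataagacc
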