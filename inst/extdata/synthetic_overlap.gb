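LOCUS       SYNOVRF01                642 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  Synthetic circular genome with overlapping reading frames
            (generated fixture; not a natural sequence).
FEATURES             Location/Qualifiers
     source          1..642
     CDS             join(571..642,1..120)
                     /gene="polA"
     CDS             91..252
                     /gene="envB"
     CDS             complement(301..420)
                     /gene="regC"
ORIGIN
        1 aagtaaccgg tactcggcga gcgcgcaact ggactggatg tcggagttgt cggactcggc
       61 gcacacatct cgctagtgtg cacatggtcc atgaaaaagc aagattataa tcaagactaa
      121 tggtgccgac cgaacaaccc tagcaacaac ttgtgcccga gtaatctata ggggtcagat
      181 aacctcgtgc taagaagttt taggagacat tagagataca acatctctgg ccccaggggc
      241 aattatagat aaaacccgcc ccacccaaca gcgtttctaa gcgcttatgc ttttatgaga
      301 ttatatcgat tcgtgttgag attcattaac cggtagattc tgtttggact cacgttatgt
      361 tctctgagaa acattgtcca aacacactta cttaaccgag ggcaagcaac gtaccctcat
      421 aacaggctcg aaccgaatag gtacaggata tgcggctcgc aatttagcgt acccgtcctt
      481 ggcatcctca ctgaactaat atcggtatgg caggagtccc actctcgcta ttctatttgc
      541 gctagaaccc cttaggagaa aacccggacc atggactcat tctgtttcac atgtccgggc
      601 tatatttgtt gggaccccta tagataggaa ctttgtacag tg
//
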