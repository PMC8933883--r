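LOCUS       SYNTH01                  420 bp    DNA     circular PLN 01-JAN-2024
DEFINITION  synthetic mini plastome fragment for parser tests.
ACCESSION   SYNTH01
FEATURES             Location/Qualifiers
     source          1..420
                     /organism="synthetic construct"
     gene            1..10
                     /gene="gA"
     tRNA            complement(5..8)
                     /gene="tB"
     CDS             join(21..50,101..130)
                     /gene="gC"
                     /codon_start=1
     rRNA            201..260
                     /gene="rrnX"
     gene            301..340
                     /gene="gD"
ORIGIN
        1 aaaactccat gtgtaactcc ggaagtagaa tcttgcactc ggcctttcca tatctcgtga
       61 accccctgca cgccctaaag tacaattagg atattcatcc ctacactgta tatgccgaac
      121 gttctaataa acgacttagc aacaagtcgc ctagaaaggt accgctggca tatcacgcct
      181 cccgcttgcc gtcttcaact tcatgaccct cgtgcatcac aaagcctcaa gccggagtct
      241 aggctttgaa acagctgaat aaatcgtgtg aatacgtgag tcgtcggaaa gcagttgaat
      301 atctaacgac ccctgcgcaa ggacacacta gtcgcccttg agagcactcc agtccaggcg
      361 aggtatccac gacgatacga ctcggctagc aaacgcgcgg tttatctatg cagctaatat
//
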