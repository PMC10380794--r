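>cathF_seed1
PQYITSMIEKQDDVMKGQIGATEQCEMGPEQDIMSMERGWWMIRFYAIVLKSTDYVQMQAKLPVLMQSSA
QVWEQWSQKKDSYPSVSQSRPLIKIARFLPSVSSTESVSMIIFAGQVELPIEMVEAMLSISVMPTDATWI
TGTEHTAGDWDDFSIFAGRPLGWSVPKDRSKDVEDSEAVFTTDKNVRKEQIWWMYDKAMEKWYWKPGSVS
PVFWVFSIFRMVSQRVFREEIWF
>cathF_seed2
PQYMTSMIEKQDDVMKGQIGATEECNMGPLQDIMSMERGWWMISFYMHVLKSTDYVQMQAKVDVLMQSSA
QHWEMWSLKKDSLPSVSQSEPLIKIARFLPSVSSTLHVSMIIFAGCVELPIEMVEAMLSISVMPTDATWI
TGREHTAGDWDDFSIFAGQKLGWFVGKDRSKDLEDSEAVFTTDKNVRKEQIWWMYWKAMEKWYWKPFSVS
PVFWVFDIFIMVSQRKFREEIWF
>cathF_seed3
PQYITSMIEKQDDVMKCQIGATEFCEMIPEQDIMSTERGDWMFRFWAIVLKSTDYVKMQAKPPVLIQSSY
QVWGQWSMKKDSYQSVMQSLPLIKIARELPSQSSTESVSMIIFAGQVELPNKMVEAMLSIRVMPTDATKD
MGEGHTAGDWDDFAIFAGRPLGWRVPKDRSKDVEDSEAVFTTDKNVRKEQIWWMYDKAMTKWYWKPGSVS
IVFWVFSIRRMVSQQVFRECIWF
>cathF_seed4
NQYITSMIEKQDDCMKGQIGAWEQCEMRHEQDIYSMEVGWWMNNIYAIVLKSTDSVQMQAKLPVLMQSSA
QVWEQWSQVDDSYPSVSQSDPRYKIARFDPSVVSKESVSHIPFAGQVGLPIEMLEAMLSISVMICDATWI
TGTEHTAGKWDDFSTFGGRPLGWVVPKDRSKDVEDSEAEFTTDKNCRKEMIWWMYDKAMEKWYYKPGSVS
PNFWVFGIFREVSQRCFREEIWF
>cathF_seed5
PQYITSKIEKQIDVMKGQIGAWEQCEIGPEQDIMSMIRGWWMIRMHMIVLHSTDYVQMMAKLPVLMMSSA
QVWWQWSQKKQSYPSVSQSCPLIKIARFIHSVSSTESVSMWIFAGDVELPIIMVEAMGSISVRPCDATWI
TRTEHTAGDWDDSSIFAGRPLGFSVENDRSKDVEDSEAVFTTDKNVRKEQIWWMFDFAWEKWYWKPGSVS
PVFWQFQIFRMVSQRPFREEIWD
>cathF_seed6
PYYITSMIEKQDDVMKVQIHATGQCEMEPAQAIMSTERGWWMIRFYAIVLKLTDYVQMQAKLPVLSQQSA
ELWEQWSQKKDSYPSVSQERPLIKILRFVPFVSSCETVSMIIFAGQAAVPIEMVEAMLSICVMPTMATWI
TVTEHTASDNDDRSIFAGRGLGWSVPKDRSKDVEDSEAVFTNDKNVRKEQIEWAYDKAMEKWYWKPGSSS
PVFWVFSIFRMVSQRVFRPNCWF
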