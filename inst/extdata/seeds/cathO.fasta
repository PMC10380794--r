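>cathO_seed1
IIMVVTQGKFSILAITGKAPEIFYCSQQALAWSWIYGLSRSSSEIDQAPGQWWETTFPIAGSIKVSTFPK
DVARMPGFGQYTDAPAAYDEDWQFTIAEPTSFPGRFTSPFSGMWIYPTREDQFRIAQSKGWTLQMITDSG
EFEHGWMPWQSAFEAMSAYFVMQREMWRAYRDLKWDVPTPGWRNQFASMGYSQQEVIPGAFFIDVFSFRI
RGAAAQDVLMAMMKDMTFAI
>cathO_seed2
IIMVVTQGKFSIPATTGKAREIFYCSQQALAWSWIYGLSRSSSEIFTAPGQWKETTFCIAGSIKVSTDPK
HVAEECGEGQYTDAPAAYDEDWINTIAEPTSFPGRFDSPESSMWIYPTREDQFRIAQPKGWTLQMITDWS
EFEHKWMPWQSAFVHMSMYFLSQREMWRAYRTLKWDHPTKGMPNQFASMGYSQQEHGPGAFFIDVFSFRI
RGAAAQDVLMAMMKDMTFAI
>cathO_seed3
IIMVVTQRKFSIIAITGMACEISLCSQQALAWSWIYPLSRSSSQIDQACGQWWETTFPIATSIKVSTFPK
DVARMPGFGQYTDAPAAYDERWQFWAAEVTSFPGRFTCPFEINWIYHTREDQFRIAQSEGWTLQSITDSP
EFWHGWMPWQSANEAMSAYFVMQREMQRAYRDLKWDVPTPGFKNQFASMGYSQQEHIPGAFFIDVFSFRI
HGANAQDELMQMMKDMTFAI
>cathO_seed4
IIMAVTQGKFSIMAIRGKAPVIFWCSQQALAWSWIYTLSRSSSEIDQADGQWMETTFPIAGSIKVHTFPK
DVARMPGFGQYTFAPAAYDEDWQFTIAEWTSFPGYFTSNFSGMWIQPTREDQFRIAQSIGWTLQMITDSG
YFEHGWEPWQTAFEAMSAMFVMQRQMWRQYRDLKWPVPTPGWRNQFASMGYSQQEVIPGAWFIDVFNFRY
RGKAAQDVLMDMMKDMCFAI
>cathO_seed5
IIMVYTQGKLSILAITGKAPEIFICYQQASAWSCIYGLSRSMSFIDQAPGQWWETTFPEAGMIKVSTFLN
DVWRMPGLQQYTDAPAAYDEDWQFTIKEPTSFPGRFTSPFSGMWIYPTREDQFRPAQSKGWTLQMITDSG
EFEHGWFPWQSAFEAMHAMFVMQREGWRAYCEAKWDVPTPGWRNQFASMGYSQQEVIPGAFFIDVFTMRL
RGAAAQDVLMAMMKDMTFNI
>cathO_seed6
IIMMVNQGKFPILAITGKAPEEFYCSLQALAWSWIYWLSRSSSEIDQANGQWWETTFPHAGSIKVSTFPK
DVARMPGFGQYTDMPTAYDADWQSTINEMKSFPARNTRDFSFMWIYPTRLDQFRIAQSFGWTLQPIVDSG
DVEHGWMKWQSYFEAMSAYPVMQREQCPAYRDSKWDVPTPGWRNQFASMGYSQQEVIAGAFFIDVFSFRI
RGAAAHDVLMAMMSDMTFAH
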