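>cathL_seed1
SEGWEMAPMQTAKKGFIQAFYYALCPTGGSVEVPSDFTWSKEWIIIQWQMSFQMTTYMLTAVDPTVIGVF
VEIPFFGQPESQTGAFWLLKSMYVMYVQYRVRMGFQQIWEKADKVDLEFIFSETWPYAAMVGIGMPDHIR
MMMSFMAKQLMQFSKVPIDLPDATPIDLLSWEMWMRGNSETPVISRDDWQIWAYAKPDERGYRRVGTFEV
FQKGSYIFFIA
>cathL_seed2
SEWWEMAPMKTQKKGFIQAFYYALCPTWGSVEVPSDFSIWKEWIIIQWQMSFQMTTYMLTACLPTVIGVF
VSIPFFGQPESQTGAAWLGKSMEAAYVQYRVRMGFQQIWEKGDKVQLEFIFSETWRYAAVVGIGMPDHIR
MMMSFMAKQLMQFSKVCIKAPDATPPDLLSWLMPMRGNSETWVISRDDTQIWAYAKFDCRPGRRVGTTEV
FQKGSYTEHIA
>cathL_seed3
SEGVEMAWMQTAKKGFIQACYYALCDTGYDVYVPSDFTWSKEWIIIQWTMSFQMTTCMLTAMDPTVIGVF
VEIPFFGQPESQTGAFWLLKSMYVMYVQYRVWMGFRQIWEKWDKVDLEFIDSETWPHSAMFGIGMPDHIR
MMLSFMAKVPMQASKVPIDTPWATQIDLLSPEMWMCGNSETPVISREDRQIWAYAKPDERGYHRVGTFDV
FQKGSYIFFIA
>cathL_seed4
SEGFEMAPMQTAKKGFIQARYCFLCPTGGSVEVPSDFTWSKEWIIIQWQMQFQMTTYTLTAVDPTVIGVF
VEIRFFGQPESQTGAFRLLKSMYVMYVQYRVRMGFQQIWMKADKVDLEFIFSHAWPYAAMVGIGMPQHIR
MMMSFMAKELMQFSKVPIDLPDATPCSLLSWEMWMRGNSETPVRSRDDWQIWAYAKPDMRGYRDVGTFEV
FQKGSDIFFIA
>cathL_seed5
SEIWWMAPMQTAKKGFIQAFYYFLCPTGGSVEVPSDFTASKEWIIIRWQYSFQMQTYTLTAVDHTVIGVG
VEIPFWGQPESFTGAFWLLKSMYVTYVQYRVRMGFQQIWEKADKVDLEFIFSETWPIAAMVGIGMPDHIR
MMMSYMAKQLMQFSKVPHCLPDATPIDLLSWEMWNRGNSETPVISRDDWQIWAYAKPDTRGYRRVGTFEV
FQKGSCIFFIA
>cathL_seed6
SEGWEMAPMATAIKGFIQAFYYALCPTGGSVEVPSDFGWSKEEIIIQWQMSFQMTLYMLEAVDPIVIGVF
VEIPFFGNPHIQTGAFWLLWSMYVMYVQYYVRMGHQQPWEKADKVDSFFIFSQTWKYAAHVGIGMPDHIR
MMMSFEAKQTMQFSKLPIDLPDATPPRLLKWEMWMRGNSETPVISRDHWQIWAYAKPDIRGYRRHGEFEV
FQKGSYIFFYA
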