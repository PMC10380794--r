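>type1_long_seed1
STTKQIWVRERLAYLRTDLGMAYWQGYSRKKKRYMDDWQRDSPEYTIGADERIRQYPWYLDSDREARYYV
PMVMWMYLVSLFAQIAVVLKGLEDWYSDWKKTGEPLQFPPSPDQVQVRGRFMPGQAAGVSPPWGPSEYVL
PRDFTWEKIPYRERIFIRAGGYAQGPSLYRTEPTPEAVRVSVSDVSWPISEQIVSSAEVEIRYAMQIQLT
QTPELQTRKISGLEYWETFPSPETKKEESVFPMLYMLKDWDYARTGSYRSPIVFQDMLFKQIILQPMVYT
ESAECEVQALPSPKWSRYYKWGFYDPKPDGWFFLYEVIIMLPKYMGLGKQYFQRQFDSEVPLPKFISRKA
RAMAGFQIWPRWGTAKQVFQKKRDPGEQLTTSLYVSFYPQIKDSKDREPWWSQRMIAKVDFRTWLKEGPP
STMKDYRTFWSRQKASIFQAKGRIQATWLEMPAGLEILGKTFPFWVWKKHTLYLITWRFVVIAQWWDQRL
LIVLWLKKLVLTSSYAVLRNMWDPFRRMDSSMIFGWLKEESIRRGVMGDDDVRWILYKWSLYVDIPGMKP
WGFIFDISKMFTWYPIEKLTQLYFSRALPWVMKLQDL
>type1_long_seed2
SYTKQILVRRRLAYLRTDPGMAYWYGYSRKKKRYMDKTQRVSMEYTIGKDEVIRQYPWSLDSDREARYYM
PMYMWMFIATYFAQIQVVLKGLEDWYSLYKWTGEPLQFIPSPDQVQVRGRFTHGQAAVVSDPWGPSEYVL
YRDFLWEKIPYEERIFIRAGGYATGPSAYRTEKTPEYVRVSVSDVDWPISEQIVSLAEVEIRYAMQTQLT
QTPSTQTRKISGLEYWETFPSKETKKEHSVCPKKGMLKDWDYARTDSYRSPIQFQDMLFVKIIVQPMVYT
ESAECEVQALPSHKVSRYYKWGEYDPYPDIWFFLYEVIIDLPKYMGLGKCYAQRQFFSYVPLPKFISVKA
CGMAGFQIWPRWGTAKQVFQKKRGPGEQKTTSLYVSFYPQIKDSKDREQWWSTRMTKKVDCSTWLKEGIP
RTMKDYRTFWSRQKASIFQAKGRIQATWLEGPAGLEILGKTFPKWVWKKHTYYLITPRYVVIDQWWDQRL
LIVLWLKKLVLTSSYAVLRNPWDPYRRMDSSMIFGWLKEYSIRRGVMGDDDVRWILYKMSLYVDIPGMKV
WGFIFDISKMFTWYPREKLTQLYFYRALWWVMKLQDL
>type1_long_seed3
STTKQIWVRERLAYLRNYLQLAYPFGYSRKKKRYMDDWQRDSPEYTIGADERIRQYPWYLLIDREAQYYV
PMLMWMYLVHLFAQIAVVLKGLEIWWSDFKKTGEPLQFPPCPDQVQVRGRAMPGQAAGVSPNWGPSEYVL
PRDATWEKIPYRERIFIRAGGYAQGWSPYRMLPTPETVRASVSDVSWPIYEQCISSAEVEIRYAMQIQLL
QTPELQTRKAEGLEYDETFPSPETKKECSVFSMLYMLKDWDYARTGSYRSYIVFQDHLFKQIGLTTMVYT
ESAECEVQALPSHSWSRYYKWGFYDPKPDGWFFLYEVIIMLPDCMGCQKIYFQRQNDSFVPLPKFISRKA
RAMAGFQVWPRCGTAVQVFQAKRDPGEHLTTSLYVSFYPQLKDSKDREPWWSQRMCAKMDFRTLLKCGPP
STMIDLRTFWWRQKASIFQAKGRIQATELEMIAGLEIPGKTFPFWVWKKHTLYLITWRFVVIRQWWCQRL
LIVLQLKKRVLTSSYAVLRNMWCPFRRMDSSMIFGWYVEESIRGGVMGDDDVRHIIYKWSLYVDLHGMKP
WGFIVDISKMGTPYPIEKLTMLYTSRALPWVKKLQDL
>type1_long_seed4
STTKQIWVPERLAYLRTDLGMAYWQGYSRKKKRYMDDFQNDSPEYTIGALERIYQYPWYLDSDRRARYYF
PMVMWMYLIDLFWQIAVVLKGLSDWQSDWKKTGEWLQFPPSPDRVEVRGRFMPGQAVFVSPPWGPSEYVL
PRDFTWEKIPWRENIGIFKGGYAQGPSKGRTEPTEEAVRVSVSQVTSPISEQIVSSCEVDIRYAMQIQLT
RTPELQIRMWSDLEYWEWFPMPETMKEESVFPMLYMLKDWDIARTGSYRSPIVFQDMLFKQIIFQPMVYT
ESAECEVQGLPSPKWSRYYKWGDYDPKPDKWFFLQEVIIMLPKYMDIGKAYFQRQFDSEVPLPKFILRKA
RAHAGFQIWPRWGTAKQVFQVKCDPGEQLTTSLYVSFYTQIKDSKDDDKWWSSHKRAKVDFATWLKEGLC
STMKDYRTFWSRQKASIFQAKGRIQATWLEMPAGCLLLVVTFFFWLWKKHTLYLITWRFVVIRQWWDQRL
LIVYWLKKLVLTSSWQVLKNMWDPFRRMDESMIFGWLKEESIRRMVMGGNDVRWILYKWSSYVDFPGMRP
WGQIFDISYVFTWYPIEKLTQLHFSRMLPWDMKLQDL
>type1_long_seed5
STTPTWWVRHRLAKLMTRDGMAYWQGYCRKKTWYMDDWQRDAWWYGIVADERIRQYPNQLDSDREAPYYK
PMVMWQDLVYLFAQIAVVGEGLEWWYSDWKKTGQPLQIPPSCDQVQVRGRFMPGQAAGVSPPIYPAEYVL
PRDFTWEKIPYRIQITIRAGGYAQGPSLYRTEITPEAVRVSVSNVSWPQMEQIVSSALVEIRYAMQIRLT
QTQELQTPKSSGLEYWMTFPPGETKKEESVFPMLYMLKDWDYARTGSYRSPIVSQDMMFKQIILQPVVYT
ESAECEVQALPSPKWSRYYKWGFYDPKPDGWFFLYEVIIMPPKYMGLGKQYVQRQFPSEVPGPKFISRKA
RAMWGFQIWPRWGTAVQWFQMQRDPGEQVTTSLPKYFYPQIKDSKDREPWWSQRLFWKVDFRTWAKEGPD
FTMKDYRTFHSRQKASIFQAKGTPQATQLEMPAGGEILGKTIPFWFWKKHTPYLITWRFVAIAQWWDQRL
LIVLWLKKLVLTSSYAVLENMDDPFTCMDSSMIATWLKEISWRRCVDGDDDLRWILYKWSFYVDIPGMKP
WGKIFDISKLQTWYPIEKLMQLYFWRALPWVMKISDL
>type1_long_seed6
STTMHIGVRERLAYLRTDLGMTYWQGASRKKKVYMDDWQRDPPEYTIGATERIRQYCWYLDSDRPARYYV
AMLMWMYLVSCFAWIAVVLKGLEDWYSDWKKTGYPAQFVCSPDGVQVRGRFRPGQARGVSPPWDPSEYVL
PRDFTWEKHPYRNRIFIRAIGAAQHPSLNRTEPTPMAVRVSVSDVSWPWSAQIASSACVEIRYAMQIQLT
QTPETQTRKESGLEYVETFFSDETKKEDSIFPMLYMLKDWDNWRTGCTRKPIVFQFMLFKEIIFQFSVYT
ESAECEVQDLPSPKWSRYYKQGFYDPKPDGWFFLYEVIRMLNKYMGLLGQYFQRQFDWEVPRPKFISRKA
RGMAGCIIAPRWGTAKQVFQKKRDPGEQKTTSLYVSFYPQIKDSKDREPWWSQRMITKVDFRDWLKEIPP
STMKDYRTFWSRQKASIFQAKGRIQCIWLEMPAGLEILGKTEPFWVWKKHTLYLITWRFVGIAQWWDQRL
LIVLWMKKLVLTSSYKVLANMWDKFRRMDWSMIFGWLKEESIGRGTMGDDDVRWILYKVSLYVDVPGMKG
WTSIFDMSIMFREYPVEKDTQCYFSRALPWVMKLQDL
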