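>cathC_seed1
PQFQSTTLSVQRWVERKRWWEKPMCMIKKVSMMEADEIFSKVPGVTRWPIMTEVIYRLSYIMYGRQRTRW
SMYPEPRPDQMWQSAMPWLSPDSRMDQQSDVSSIASAMAMQRYYRKIWYRMFIPSIAQEPEDMAPKGVSI
KAIEHMPQEWIYWEKFWQVVLERQEPLVPFAVYIMQIIIGLPAQNYGIDVKWMEAYYYVYQLYIKYPKTR
KDLGAPVDMMVWWSTGGIDALLY
>cathC_seed2
PQQQITTLSVQRWVGRKRWKEKIMCMPKKPSMMEADEISSKVPGVTVWFIMTEVIYRLSYRDYNRQRTQK
SMYPEPRPDQMWQSFMPWLSPDSRADVQSDVSFIAEAMAEQRYYRKIWYRMFKHSIAQSPDDMAPKGVEI
KAMSHMCQEWFYWEKFWQVVLERQEPLVPFAVYIMQIIIGLPAQNYSSDVKWMEAYYYFYQLYIKYPKTK
DDLGAPVDMHKAWSTGGIDALLY
>cathC_seed3
PQFQSTFNSVQRWWEPKRCWEKPMCHIKKVSVMEADEIFSKVPGVTRWPIMTEVIYRLSYLMYGRQRTVW
GMYPEWRPDQMWQSAMPWLSPDSRMIQQSAVSSIASAMAMQRYYEKIWYRMFIPSIAQEPEDNRPKGNSQ
KAIEHMCAEWIDDIKWTQVVLERQEPLVPFAVYIMQIIIGLPAQNYGIDVKWMQAYYYVFQLYIKYPKTR
KDLGAPYDMMVWWSTGGIDALLY
>cathC_seed4
PQFQSTTLKVQRWVEKARWWEKPMCMIGKVSMMEADEIFSKVGGVTRWPIMTEVIYRLSYIMYYRQRTRW
SWYPESRTDQMIQSAMPDLWPDSRMDQQSDVSSIASAMAMQRVYRKCWYRMFIPSIAQEPHDMAPHGVSI
KAIEHMPQEWIYCEKFWQVVLVEQEPLVPFAVHIMQIIIGLPAQNYGWDVMWMEDYYDVYQCYIKYPKTR
KPLGAPVDMMVWWSTGAIDAPKY
>cathC_seed5
PQFQSTKLSNQPWVERKRWWPLCMCMIKKVSMREADLWTSCVPGVNRWPIMTEVIHRLSYIMAGRQRVRW
SMYPECRPDQMWQSAMPWLCPDSRMDQMSDVSSIMSAMDMQRYYRKIWYFVFSPRIAQEPEDMAPKGVSI
FAIEHGPQEWIYWAKFWQVVLERQEPLFPFAYYIMQLIIGLPAQNYGIRVKWMEAYYYVYQLYAPYKKTR
KDLGNPVDMMVWWCTGGIDALLY
>cathC_seed6
PQFQSTFLSVQRDVERKRWWMKPMCMIKKVRMMEFDEIFSKVPGVTRWPIMTEVIYRLSYIMYGRQRTRW
QMYPEPFPDQMWQSAMPRLSPDSRMDQQCDSSSIASAMAMQRYYRKIWYRMFIPSFAQEPEDMAPKGVSF
KAIEHMPQEWIYWETFWQVVLVRQWPLVPFAVYIMSIIIGLPAQNYGIDVGWMEARYYTYQLYLKYPKTE
KDLGAPVDMMVWWSTGYIDALLY
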