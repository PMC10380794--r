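>p26_29_seed1
WASDEGVDKRQRARGVRKDVTSQKEYSRWERQGGWDVKSGYPFRESRYAFQSLAKLYTIQRIVPQIREMP
VFVSWMIGVQRKTDYVSVSSDEAYPKTMMIQRVSYWLRWQQVWLIDVTRATERQRFDFATLRPFWPEWFR
DIKMQTTFKTELRVCGFTFWEEETADMQWTRKMSGRERRRRDQQARWDKGWQWISLKFEWKSASQQILWK
KDVMSFLRSPIMVSSGRSESIIVRAWMRTRQAKVLADWSITTAIVMRTAFRRASGVKMIPMVTHAREKDT
FMEWMSTYMWMPLYIGQLPVGDSGKTQSMFLRSNYMMDYPDRQQASRDLSIDDVWVRYRPLVQLTQELFK
AATSARSSPK
>p26_29_seed2
WASDEGVDKRQRARGVRKDVTSQKEYSRWERQYGWDVLSGYPFDESRYAFQSLAKLYTIQRIVPQIREMC
VAVSAMIGVQRKTDYVSVTSDAAYSKTMMIQRASYWLRWQQVWLIDVTRATERQREDFATLRPFWPEWFR
DIKMQTTFTTFLRVCGFPFWERTTADMQWTRKMSGREGRRRDQQARWDLGPQWISVKFEWKSGSEQILWK
KDVMSFLRSPIMVSSGRSESIIPRMWMRTRQAARLADWSITTAIVMRTAFHRASGVKMIRMMTHAREKDT
TMEWWSIYMWMPHQIEQLPVGGSGKTFSMFLRSNYMMDYGDRQQASRDLSINDVWVRYCPLVQLTQELFK
AAGHARSQPK
>p26_29_seed3
LASDEGVDKRFAADGVRKDVTSTKEYSRWERQGGWDTKSGYPFRESRYAFMSLADLQTIQRIVPQIREMP
VFVSWMIGVQRKTDYKEVSSDQALPKPMMGQRVDHWLRWQQVWLIDVIRATEDQRFGPATLRPFWPEWFR
AIKMQTTFKTELRVCGFTFFEEYTAGGQWTRKMSLRERRRRDQQARYDLGWVWISLKFEWKSASQQILWK
KDVMSFLRSPIMQSSGRSESGNVRAWMRTRQAWVLADWSINTAIVMRTAFRRASYVKVIPMVDHAREPDT
FMPWMSTYMWMPLYIGQNPVGDSRKSQSMFLRSNYNMDYPDRYQASRQLSIDDVWVRYRPLVQLTQELFR
AATSARSSPK
>p26_29_seed4
WANDEAVLKRQRMRGDSKDVTSQVEVSVWERQGGPDDKSGYPFRESRYAFQSLKKLYTIQRPVPQIRERY
VFADWMIKVQRWNDYVDVSSDEGYPKTWMIQRVSYWLRWQQVWLIGVTCATKRQRGDFATLRPFKPEWFR
DYKMQTTFKFELRQCGFTFFEEETADMQWFSKMFGRERRRRDQDARCDKGWQQVSLSFEWKSAHQQILWK
KDVMSFLRCPIMVSSGRSESIMVGAWMRTRQAKVLADWSITTAIVMRTAARRASGVKMIPMVTHAREKDT
FKEWLSTYNWMPLYIGQLIVGDSKKTQSMFLRSNYMMDYGDRQQASESPSIDDVWGRYRKLVQLTQCLFK
AATSARSSPK
>p26_29_seed5
WASDEGVDKRQRARGVRKDQTGQKTGSNKERQGGWDVKTGYPFSESRYAFVSLAKLYTIQRIVPQIREMA
VFHSEMIGVQRKTIYVEVMSDEKYPQTMMIQLVSYWMRWQQVWLWDVTRATERQRFDFATLRHFWPEFFR
DIKCQTTFKTELRVCGFTFWERETADAQWTRKMSGRERFPRRQQARWDIGWQWISLKFEWKSASQVWLWK
KDVMSFAHSPIMVSSGSSESIIVRAWMRTRQAKILKDCSITTAIVWRTAFRWASGVKMINMVTHAREKNT
FMEWMSTYMWMPLYVGQLPVGDSGKGQSMFLRSNYFMDYPNRSQANRDLSIDDNWVRYRYLVQLTQELFK
AACSARSSPC
>p26_29_seed6
WWRDSGVNKRSRARGVRKDVTMSKEYCRWEDQGGWDVKSDYPFRESRYAFQSLAKLYTIRRIVPQIREMP
VFVSWMIGNQRKTDYVSLSSDEAYPRLMMIQRVSFWLRWQQVWLIKVTRATVRQRHDAATLWIFWPEWFS
DIKNQTTFKTELRVCGHMRALEEEADQQWVRKMSGRERRRRDQQARWDKGGQWISLKFEWPFASDQILWK
KDVMSFNRSPGMVSSGREESIFVRAWMRTRQNKVLHDWSIITAIVMRTAFSRASGVKMILMVTHIREKDT
FHEWMSTYMWMPLYIGQLPVGVSGKTQNMFLRSNYMMDYPDYQQASRSLSIDFVWWRDRPLVQLTQELFK
AATFAASSPK
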