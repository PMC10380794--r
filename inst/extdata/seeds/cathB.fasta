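>cathB_seed1
ARTGFFPVISATPMTRSQKFWIIDCRWGWRKKIKDQRVPGQELIGQMTWKQIIWYGFPPTGSTTFTEGWK
WLWSPASATGAVKVLKWKSDDSFRMGWSQGVEKKPLIQRVFQPYVVELADARQPESVMIWTVQWMDISVT
MIDYTASKVYAYLVYGSHRMTFEMPLRQSISSWFLSGYISPFEPMEFAWTEQEEAYLNRKVRVMKKMLLV
AQGWEWQFPMAGIQFKFLLGGSIIWGYAYWFPKVSTDFEAKDKP
>cathB_seed2
ARTHFFPVISATPMTRSGKFWIIDCRWKMRKKIKLQAVPGQELIGQMTWKQIIWTWFPPFGSTTFTEGSV
WLWSPAKATGAVKVLKWKSDDAFRMGWSQGVEKKPWIQRVWQPYVVERADARQCESVMIWTVQWMRIFVT
MIDQTANKKYAYLVYGSHRMTFEPQLRQSISSGFLSGYHSQMEPMEFAWTEQEEAYLNRKVRNMKVMLLV
ARGWEWKFPMAIAQFKFLLPGSIIWGYAYWEPKTSPDFHAKIKP
>cathB_seed3
ARTMFHPVISWCPMTRSQKFWIRDCRWGWRKKIKDQRVPGQELIGQMTWKQIIWYGFPPLGSTTFTCGWK
WHWSPASATGAVKVLKWKSDDSFRMGWSQGVEAKPLIQRVFQPYVVELADARQPESVMITTVQWMRISVT
MIDYTASKVYAYLVYGIHRMTFEMPLRQSISSEFLSGPICPFECMELAWTEQEEAYLNRKVRVKKKTRLV
AQRWEWSFPMAGIQFKFLLGGSIIWEYAYWWPKVSTDFVAGIKP
>cathB_seed4
ARPGFYRVISATPFTRWQKFWIIVCRQGWRTEIKDQRVPKNELIGQMTWKQIIWYGFPPTGSTTFTEGWK
WLWSPASATGADKVRKWKSDDSFRMGWLQGVEKKPLDQRFFQPYVVELADARQPESVMGWTVQWMDGSVT
PSDATAWKVYVYLVYGEHQMLFEMPNRQQMSSWFLSGYISPFEPMEFAWTKQEESYLNRIVRVMKVMLLV
AQGWEWQFPMAGIQIKFLTGCSIMWGYAFWFPKVITDYEAKDKA
>cathB_seed5
IPTGFFPVISATPMTRSQKFWIIDCRWAWRAKIKDQRVPGQELIGQMTWKQIIWYGFPPTGTTEFTEGWK
WLWSPASATGAVKVLKWKSDDSMSMGWSQGVNKEWPIQRVFQPYVVRLADADWPESQMIVTCQWMDISVG
MIYYTASKVYAYLVYGSHRMTFEMPLHIAISAEFLSGYFSPFKPMEFACTEQEEAYQNRKVRVMKKMLLV
AQGWEWQFPMAGIQFKFLLCGSIIWGYAYWFPKVSTDFEAKDKP
>cathB_seed6
VRTGFFPVISATPMTRSQKFWIIDCRWNWLKEIKMQRVPGQELIGDKDWKQIIWTGGPPTGSTTFREGWK
WLWSPMSCTGAVKVLKWKLDDKERMGWGQGDEKKPLIQRVFGPYVVELADARSPELVMIYTVQWMCISVG
MIDYEASKFYAYLVYGSHRMTFEMPLRQSASSGFLSGYMSPEEPMEFFWTEQEEAYLNRKVRVMKKMLLI
AQGWTWQFPMAGIQFKFLTGGSIRWGYAYWFPKVSTDFKAKDKP
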