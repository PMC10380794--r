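>cathX_seed1
WAERRYRMQQYLAPMFAKFLMQIDCGGKSFDMVGMYSWQEIPVPFGPGKYKEKKYKVWFVRAYQMISEKV
IRGSKTRQTYAGSKWLQWSRPVTITSTMSGKRQYQAQGRFAYRGVKIKYQWKQLKLYWTTEYWLTLPDEV
SQIELGPDWQHVDDDDGVPEDRGIALSIPQPRLKRDEVWAAETWLEFDVDNYISRYEDKDTKQGEGDAKA
MGSPMSYSWQTSFDRTSMARDMDRDWDMAYPK
>cathX_seed2
WAERRYRMQQYLAPMFAYVLMYIDCQGKSFDEVGMYSWQRIPVPFGCQKYKVKKYKVWFVRAYQMISEKV
QRGSKTRQTYAGSQWFQWSRPVTITSTMSGKRQYVAQGRDAYRGVRIKYPWKILKLYWTTEYWLTLPDMV
SQQELGPDWQHVDDDDGHPEDRGIALSWPQPRLKYDKVIAAETWLEFDVDNYISRSEHKDTKQGESDAKA
MGSPMSYSWQTSFYRTSMARDMDRDWDMAYPK
>cathX_seed3
WWERRYRMQQYLARMWQKFLMQEDCGGKSFDQVGMYSWQEICVPFGPGKYKMKKYKNWFVRNYQMISEKV
IHGSKTRQTAAVSKWRQPSRMVTITSTMSGVRQYQQQGRATYRGVKIKYQWKQMKLVSTTEYWLTQPDEW
SQEMLGPDWNHVDDDDGVPEDRGIALSIPQPRLKVDEVWAFEMWQEFDVWNYISRTEDKDTKQGEGRAKA
MGSPMSYSWQTSFDRTSGARDMDRDWDMAYPK
>cathX_seed4
WAERFYRMAQYLWPMNAKFLMQIDCGSKSFDMVGMYSWQEIPVPFGPGKYKEPKYKTWFVRGYQMIYETV
IRGSKTRQTYAGSSWLNWSRPVTITMTRSGKYQYQAQGRFAYCGVKWKYQWGQLKTYWTTEYWLTLTDDV
YQIEDGPDWQHVDFDDFVPEDRGIALSIAQTRIKRDAVWAAETWLEFDVDNYISLYEDKDTKQGEGDAKA
MYSPMSYQWQTSFDKTSMARHMDRDWFMAYPK
>cathX_seed5
WAERRYRAQQYEAPMFAKFLMQIDCGCKSFDMCGMYSWQEIPVPFGPGKYKEKKYKVWFVRAYQMISEKV
IRGSKTRQTYAGSKRLAWYIPVTITSTMSGKRQYQAQGRFAYRGVKIKYQWFQLKGYWTTEYWLTLPFEV
SQKELGCDWQHVDDDPPVPEDRGIALSIPNPRLKRIEPWANGTILEFDVDNYISRYECKDTKQGEGDAKA
MGSPQSYTWQTSFDNTSEARDMDRCWDMAYPM
>cathX_seed6
WAERRYRMQQELAAMFAKFLMQIDCGGKAQDMVGMCHWQEIPLPFYPGKYKEKKYKVWFDRADQMISEKV
IRGSKTRQTYAGSKWLQWSRPVTITSTMGDKRQSQAQGRFAYRGVKIKYQIKWLMLIWTTEYWLTLPDEV
SQQELGPDPKHVDDDYGVPEDVGIALSIPQPRLPRDLVWAAETWLFFDVDNYISRYQDKDTKKGYGDAKA
SGPPMSYSGQTSFDRTSMALFMDRDWDMAYPK
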