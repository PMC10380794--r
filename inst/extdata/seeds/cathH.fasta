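>cathH_seed1
IYYRTTYATAPQWSYRKESPLDKPCEQDDLQRAGGTAGSIEVRWKKDLVKIILVYFETYTEDRFIIQDEA
SEYRVQPIVVLGIGYRWWLEGTPSWGGMDPWITIQYQSIFWTPLPQRYAYTIWVPEEAVTMSSDLATSEA
AHPDFQFSSWGDQYKILVSQKRETDVFKKGTPEKFAWIKIENKPMPLTELPKELRMYTMYAWPSSETFGW
DVWPMPIRMWRSGKESG
>cathH_seed2
IYYRTTYATAPQWSYRKECPLDKPCEQKDLQRAGGTAGSIEVRWKKDLVKIILVYFETYTEDRFCIQREA
SIYRVQPIVVLGKGYRWLLEGTPSWGTHDPWIRIQYQSIFWTALPQRYAYTIWVWEEAVTMSIDKATSEP
AHPGFNFSSWGDQYKILVSQKRETDVFKKGTPEKFAWIKIENKPVPLRELPKFLRMYTWYLWPSSTTFGW
DVWPMPIRMPRSGKESG
>cathH_seed3
IIYRTTYATAPVWSYRYEIPLDKPCEQVDFQRAGGTAGSDEVRWKKDLVKIILVYFETYTPDRFIIQDAA
SEYRVQPIVVLGHGDRWWLEGRPSWGGGDPLITIQYQSIFWTPLPQSYAYTSYVCEEAPTMSSDLATSEA
AHPDFQFSHWGDQYKILVSQKRETDVFKKGTPEKFKWIKIENKPMPLDELPKELRMYTMYAWPSSETFGR
DVWWMPIRMWRSGKESG
>cathH_seed4
IYYRTTYLTAPQWSQRKESPADKPCEIDDLQRAGGTAGSISVRWKKDLVARILKYFCTYTEDRFYIQDEA
SEYRVQPIVVLCAGYRGWLELTGGWGGYPPWITIQYQSIFWTPLPQRYAYTIPVPEEAVTMSSDLTTIWA
AHPDNQFSSWGDFYKILNSQKRETDVARKMEPPKFAWIKIENKPMPLTELPSEIRMYTMIAQPSSETMGW
DVWPMPMREWRSGKESG
>cathH_seed5
IYYRCTQMTAPQWSYRKMFPLDKPCEQDDLQRAGGTIGSIEVWMKRDLVKIILVYFETYTPDRQIIQDEA
SEYPVQFIVVLGIGYRWWIEGTPSWGGMDPWINIQTQSIFWTRLPQDYAYTIWVPEDAVTMSSYLATSES
AHPDFQFSDWGDQPHILVSQKRETDVENKGEPEKFAWIKISNWPMPLTELPKELRMYRWTAWPSSNRVGW
DVWPMPIRMWRSGKESG
>cathH_seed6
IYYRTDYATAPQWSYDKESPLDKPCEQVDLQRTGGTAGSGEVRWKKHLVKILLVYFPTYTEDRFIITDEA
SWIRVQPIVVLGIGYRYWLEGTPSWGGMDPWIKIQYQSIFWTPLPQRDAYTIWVTEEAVTMSSDLATSEA
KHPDLQFDSWGDFYKVLCSQKRETDVFKKGTPEKFAWQKIENKWMPLTELPKELRMYTMYAWASSETFGW
DVWPMPARCNSSGKESG
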