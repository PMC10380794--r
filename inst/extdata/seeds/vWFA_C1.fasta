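>vWFA_C1_seed1
FKGDIIRLKSSTTMAFPYLPILRKQWTTYPSPVKQMDRPVKGRLGMPAAFQGLPDWLQALYSQFMVSFPP
KQRGEQRPQLEAYRTFRWTDPEFTAWKVKSGFEVIPTYLMQVWMKGDYPDTPDDLFWLISEEAGKMESSE
PQFPPQRLPWWIIPYKLDMVLQVYADTPKFLYASMPDITRWSMKLVIGDEYIKRMSMRVQKGYACDLRWK
DFKWWWSWSFKPSMWQLMEFPVLMRGDSPMALWQRWKLRWGLMYDLFQIYLGYVQQTSDDYSRLIMVIPL
TWKLMTFKMDEMFDWFYIAIKYQMPDTLDRKGRPAYMGSSADQGSSASMMASTSWHYLTFQFYMMWQKED
GSTYSPPKRIIWYMAGSKSVYAFDINWQGMRAYPIPELQEPWWGVWPYEQEGTQKPTQFVFSMEGGQDFV
FIALKTWKMK
>vWFA_C1_seed2
FKGDIIRLKSMTTMMGPYLPILCKRWTTAPSPVKQMDRPVKGRLVMPAAMQGLPDWLQSLYSQFMVSFPL
KQRGEQRPQLEAYRTFQWTDPEFTAWCVKKGFEVQPTYLMYVEMKGDYPDTPDDLFWDVSEEAGKMPSQE
AQFPPQRLPWWIIPYQLDMVLQVYADTPKFLYASMPDSTRRSMKLVIGDEYIKRMSMRVQKGYACDLSWK
DFKWWWSKSFKPSMWQLMEFIVSMKGDSPMKLDQRWKLRWGLMYDLFQIALMYVQSTSDDYSRLIMYIPL
TWKLMEFKMDEWSDWFYIAIKYQMFITATRKGRPAYMGSPADQGSSRSMMTITSWHYLTFYFYSMWQKED
GSTYSPPKSIIWMMAGSKSVYAFDINWQGMRAYPIPERQWKWWDEWIYEQEGTQKGCQFVFSMEGPQDFQ
RIALKTWFMK
>vWFA_C1_seed3
FKIDIINLKSGTTMAFPYLPGLRKQWGTYPSFVKQMDRPVKGRSGMPAAFSGLPDDLQWLYSQFMVSFPP
KQRGEQRPQLEAYRDFKWTPPPFTAWMVKSGFEVIDMMLMQVEMKMDYPDTPDLLFWLISALAGKMASSN
PQFPPGRLPWWIIPYPLDMVLQVYADWPKFLYASMPDITRWSMKLVIGGEYIKRRIFRVQKGYACDLRWK
DFKWWCSMSFKPSMFQLMEFPVLMRGDSPMALWQVVKLRWGLMYDLFQIYLGYVQNTSDDYSRLIMVIPL
TWMLMTFKMDEMFDWFYVAIKMQMPDTLYRKGRPAYMGSSADQGSSASMMNSTSWHYLTFQFYMNWQKED
GSTYSPFKRIIWYMAGSKSVYAFDINWQGSRAYPLPELQEPWWGVWPYEQEGTQKPAQLVFSMEGGQDCV
FDILKTWKMF
>vWFA_C1_seed4
FKVWIERLKSSTWMAFPYLPRLRKQWTTYPSPVKAMDRPFKGRLSMKAAFQGLPLWLQALYSQFMVSFIP
KQRGESRPQLMAYRTFCWTDPMFTAWKVKSGFEVIPTYLMQVWWKGDYPDKPDKLFMAISEEAGKFESSE
YQFPPQFIPWWIIPYKLDLVLQVYADTPDFLYAVDPDITRWSMTLVIIDETIKRMSMRVQKGYACDLRWK
DFKWWFSWSFKPSMWQLMEFPVLMRGKMPMKLWQRWKLRWGLMYKLFQIYLLYVQQTSDDWERPIMVIPL
TWKPFHFDMDEMFDWFHIALKYQRCDTIDRKGMPAYMGSSADGGYSASMMASTSWHYLTEQFYMMWQKED
GSTYSPPKRIIWYMAGSKSVEAFDHNWQGMRAEPIPELQYPWWTVGPYSFEGGEKPIQMVFRMEGYCDFV
FIQLKTWKMK
>vWFA_C1_seed5
FYWDIIRCKSSTTMAFPYAPIIRKCWTTYPSPKKQMDRPSKGSLGMYAAFFGLYDWLQAEKSQAMVSFPP
KQRGEQRPQLEAYRTFPWYKPEFTAWKVKSGFEVIPTYRMQIWMKGDMPDTPDDLFWRISEEAGKMEGSE
PQFPKQRGPWWIIPYKLDMVLQYYADAPQFLYASMPIITRWSMKLVIGDEYIKNMSMRLQKGYACDLRWK
DFKWWWSWSFKPSMVQLMEFPMLMRRDSPMARWQVWKLRWRWYYGLFQIDLGYVQVTSDDYSRLIMVIPK
TWKLMTFKMDEMFDWFMISCKYQMPDTLDRKGMPAYMGSSADQWSSASMMAKTSWHYLTFQFVMMWQKED
ESTYSPPDRIIWYMAGSKSVYAFDINWQGMRAFPIPEQQYPWWGVWPYEQEGTQKPTQFVFSMEGGQDFV
FIELKYWKMK
>vWFA_C1_seed6
FKCDNIRLYSSTCMAFPGLPILRKQGTTYPWPVKQMDRPVKGRLGCPAAFFGLPDWLQANYSQFMVSFPP
KQRGEQRPQLEAYRQFRWTDVESTAWKVKSGFEVIITYLMQVGMKGDYPDTPDDLFWLISEEAGKMESSE
PNAPPQRLPWWIIPYKLDAVLQVYADTPKFVYASFPDITRWSMVLVQGDEYIKRMSMRVQKAYACDLRWK
DFKWTWSWSFKPSMQQLMELPVLMRGDSPMALWQRWKLRWILMYDVFHIYLGYVQQTKPDYSRLIMVSPL
TWKGMTFKMDEMFDWFYIAIKYQMPDTLDKKYRPAYDGSSADQGSSASMMDSTSWHYLTFQFYMMWQKED
GSTYSMPKRIIWSMAGSYSVYAFHINWQGMYAYPIPELDEPWWLVWPYEQEGMQKPTQFVFSMNGIQDFV
FIALSTDKMK
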