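>qb_g1
RFGRASQYGHASVGYLAAGAAGYRPVRRVSTDEGFTVSIDCSYPERRTLTIMSVFRGRIWEGWRDHPHWYATKHPIPLSSRFTLVRRNRDLSFSLCRLPVLSPLVVPHTCGALVYTVHNPTPRPRHILACFLGSLPVPSGYRPVPFTWTPHSTKGCNRLQVEDPRHECLTHSSGGRLALAPAFILYHSVTTDSIAKWPVLLQSVHDHAIGIAPLSMRLRNSPGYLSTIHRAWPRQLVEKRRCLNSSASLWTFYGSRGSNRLLNSLRRSKGGISYQSSCSCFLMDQACQMRGKKTRINWSA
>qb_g2
RFARASQYGHDSVGFLAAGAAGYRPVRRVSTDEALTVSSDSCYPERRTLTIMGGLRGRIWESWSDPPNWYATQHPIPLSSRFTLVRRIRDLSFNLCRLPVPSPLVIPHTCGALVYTVHIPTPRPRHILACFLVFLPVPSRYRPVPFTWSPHSTKGRDRLQLEDPRHECLTHSPGRRLLLAPAFILYHSGSPHPIAKWPVLLQSVHDHAIGIAPLSIRLRNNPGNLSTIHRAWPRQLVGKRRYLNSSASLWTFYGSRRSNNLLNTLRRRKGGISSQGSCSCFLMDQACQMRGKKAWINWSA
>qb_g3
RFARASQYGHDSVGYLAARAAGYCPVRRESTDERFTVSSDSSYPDRRSLTIMSVFRGRIWDGWSDHPNWYATQHQIPLSSRFTLVRRNRDLSFNLCRLPVLSPLVIPHPRGASVYTIHIPTPRPRHILTCFPGYLPFHSRYRPGPFTWSPHSTKGCDHLQLEDPRHECLTHSPGRRLLLAPAFILYHSVSSDSITKWPVLLQSVHNHATGIAPPSIRLRNNPCNLSTIHRAWPRQLVGKRRCLNSSASLWTFYGSRGSNYPLNSLSRRKGGISYQGSCSCVLMDRACQMRGKKTRINWSA
>qb_g7
RFARASQYGHDSVGNLAARAAGFRLVRRESTDEGFTVSSDSSYPERRTLTIMSVFRGRVWDGWRDHPNWYATQHPIPRSSRFTLVRRNRDLSFNLCRLPVLSPLVIPHTRGALVYNIHIPTPRPGHILACFLGILPVLSRYRPVPFTWSPRSTKGCDRLQLEDPRHKCPTHSPGRRLLLAPAFIFNHSVLSDSITKWPILLQSVHYHAIGIAPLSRRVRNNHGNLSTIHRAWLRQLVGKCRCLNSSASLWTFYGSWGSNYPRNSLRRRKGGISCQCSCSFFLMDQACQMRGKKTPINWSA
>qb_g8
RFARASQYGHDSVGYLAARAAGFRLVRRESTDEGFTVSSDSSYPERRTLTIMSVFRGRVWDGWRDHPNWYATQHPIPRSSRFTLVRRNRDLSFNLCRLPVLSPLVIPHTRGALVYNIHIPTPRPGHILACFLGILPVLSRYRPVPFTWSPRSTKGCDRLQLEDPRHKCPTHSPGRRLLLAPAFIFNHSVLSDSITKWPILLQSVHNHAIGIAPLSRRVRNNHGNLSTIHRAWLRQLVGKRRCLNSSASLWTFYGSWGSNYPRNSLRRRKGGISCQCSCSFFLMDQACQMRGKKTPINWSA
>qb_g4
CFARASQYGHDSVGYLAARATGYRPVRRESTDEGFTVSSDYSYPERRTLTIVSVFRGRIWEGWSDHPNWYATQHPIPLSWRYTLVRRNRDLSFNLCRLPVPSPLVIPHPRGALVYTIHIPTPRPRHTLACFLGIIPVPSRYRPVPFAWSLHSTKGCDSLQLEDPRHECLTHSPGRCLLLAPAFILYHSVSPNSIIKWPVLLQSVDDHAIGIAPLSIRLRNDPGKLSTIHRAWPCQLVGKPRCLNSSASIWTFYGSRGSNNPLNSLRRRKGGISCQGSCSCFLMDQARQMRGKKTRINWSA
>qb_g5
CFARASQYGHDSVGYLAARATGYRPVRRESTDEGFTVSSDSSYPERRTLTIISVFRGRIWEGWSDHPNWYATQQPIPLSSCFTLVRRNRDLSSNLCRLPVPSPLVIPHPRGALVYTSHIPTPRPRHILACFLGIIPVPSRYRPVPFTWSPHSTKGCDRLQLEDPRHECLTHSPGRRLLLAPAFILYHSVSPDSITKWPVLLQSVDDHAIGIAPLSIRLRKDPGRLSTIHRAWPRQLGGKPRCLNSSASLWTFYGSRGSNNPLNSLRRRKGGISCQGSCSCFLMDQACQMRGKKTRINWSA
>qb_g6
CFARASQYGHDSVGYLAARATSYRPVRRESTDEGFTVSSDSSYPDRRTLTIMSVFRGRIWEGWSDHPNWYATQHPIPLSSCFTLVRRNRDLSSNLCRPPVPCPLVIPHPRGALVYTSHTPTPRPRHILACFLGIIPVPSRYRPVPFTWSPHSTKGCDRLQLEDPRHECLTHSPGRRLLFAPAFILYHSVSPDSITKWPVLLQSVEDHAIGIAPLSIRLRNDPGKLSTIHRAWLRQLVGKPRCLNSSAILWTVYGSRGSNNPLNSLRRRKGGISCQGSCSCFLMDQACQMRGKKTRINWST
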