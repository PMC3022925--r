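>G001_S288c
MKIQKGYKMVKFTSRGRTHGAIQTSIGFCKGEHTLKSPTSGSCKSLMDSWTHTIFAVCICTRASTGVTSAIALYWSGWLSPHNVGIRGVASTFLVALLPAGGFGAATVLPTRCPRVRHGAVVLNR
>G001_hom01
NFIHKGGKMVKFRSRWRQHTAINTKIPFCYAEVTCKVVDSGSCKYLMNYHWHTIFANMYCFEISPGVTHAIFINESGYCWPHIVGSRPVCETVLVTLHPAMGVGLATVFPTQCCRVDTGAVKEIC
>G001_hom02
WSCQQGHRRSIQEYPWRTPSAIKTMCAFDKGRRTLAYPTHGNQKSNQDMWTHIIFALCISYEPSTIVEQAMATLRSKPLSPMLICKSWGYAIYLVAYLPEGGRPNKTVSPTRAPRVRHGGVVDPR
>G001_hom03
FKYDYRNAMVGFQNRGHQHNLIQTSIHFNHTEHILKSYHSSSFKFVGFPWPHTLIAVSLINRAQIGVTPWGAMYWSGSLTCHPVGITGCASTWPVALLPAGGFGTAMVLPTRYPTVRDGWVNDHL
>G001_hom04
MKMCIGYPQVKFRWGGRTNHIIQTSIGFRKHWAYLKIPMSAGGKSLCDHATHTWFWVHRCLSCSEIVTSWKAIQWQEVISPHTDGYFDVESGMLVAYLCTGFFGAATVLITLCWRVAWGTVVGNH
>G001_hom05
CMIGMHHKMVLQQFVGRTWWKIQTSIGIADGPKTEGYDDVIQMKDLPNSMTHTWCANCICTRASTCIISWIATDWSGYTSDHNVRINCVAKAELVALLPFIGFGEATQLGIRTLRRYHGALIPCR
>G001_hom06
GKLCIGYKVVYCTNRWVWNANYYDQIRDKFGTHCLKVPVEGYPKSFMVSGTMTIFICEICNIAQTKPEWTIALRSRAEMSDHNVLWTNVFSGCCVYMQDYGRAWAAQSLNTMCFRIRHGARNFTR
>G001_hom07
MKIDSHEKKVNSLSEGRTHQFIQHERGFAMGEHTWKSCTMNGKKSLDDSWERDVFSVCICRSKSTGWWMAIWLAWEGWKSKHQHGIFFANDADVVALLETGGFGAAMWDESELPGWRNGAWWYVQ
>G001_hom08
MDIQKGYKNFWFTERSRLCGKIQVSCQFCRYEGEDKRPCSGSLKRQNDQWPLRLFMVQISTCASTWVFSAIKLYDSMWLSEHNTQIRSVASDVLMAKGPFGIYGAATQHPTRGPRIQHGECVANY
>G001_hom09
PSIRKSYNMSCFTSSGRTHGHIQDSIGFCDDMHTKKDPTSGGCQSLMKSWLDNICAHCIQEHVPTGFNFARAMYKSMMKSPMGPGKRKVFSTSLHTKLPDKKPSIWGKLPFRFPKFRNEVMVLIE
>G001_hom10
CDWKKNEKMVNHTMQGYTEGAIMYSHKREYGKINSDSKEDGHYKKLMDSYTHTLFAVQSVNHASTGVTSRPADVWSGHMCTVLVGCRGIASTFPRALLPHGWFGKITVDIRRCSVVRFKAAVKRR
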