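>G013_S288c
MLRLNTGKTATCLLTSPQRRSILHPLGELTDSFLVLYWAWSGCRVRKGAGCHSLNLVARLRIMIECLRAILEFSRVGYEQDRQEITPKLIPPTGSIWPSPHIWMLGYGNGSRPLMKSKPKLPVTIAHVCLLLFTDC
>G013_hom01
MCSCNYEKSATNLLTNSKRQSILHPPIDLADFIDAGLFSWAGCNVRKGGGCHACNTPAGLMVWWECYKAPLSVHCVSHEDDRERDTPKYIPPTMFIWPSDHMMLLNYINGSFWLMRGYVKFAVIYAHRCFLIFTNK
>G013_hom02
LNRCNTVKTHTAYEYSECSRSEWHPTGIHTDSFLFMYWFNSGFVVRKGCQCNSPALVTRLRHEIECVGAILWFHRSLPIQDAVHMGPFLPPGTGFIWLSPVIHKYHPQPISTPLESSKRPYPVSKAHVLGLPVQEC
>G013_hom03
CVEFNTGKTNTKLQVSPQRAFIQHPLIGLTDSFLALYWVWSGWRCRHNKGCIKLPFVDRLPPEKNKSWALMENGRWQHEEDWGSITWKVIPPCGMFWRSPHIQEFGYGNGSRGLMNSKPKLPVQVAHVCGSLIMDN
>G013_hom04
SLRYMSGDLAPCICRKPQRRSWLQRMYYDFVSHAVLFMPWFACYNQMRQGCQSKSQPYYLERIHENLRAITLTSHVGFINDSQEITMKLIKPTGSINPSHHIGFLVYWEGTCPFMTSMTLYSVTINYYIRLYFMDH
>G013_hom05
TLRMNTMEHGTALLTSEQQRSGYCPLGYLTDSFHVEVQVLSVPDHHKGMGCAMLNGLAMLMLFTEVLREILDWDRVGYEQDRDEADMKLQYPTRSLEWSIHSWMLGYGNSSHDMMKVVDILPVTIAYVGRDLFTEC
>G013_hom06
RLSLWKDKHAPVLLTSWSTRRHLNPLGELRGAMCTLYRHWHACFVRYGGDCHMLNWEARCRAYIYVHRATENPSRVGYQKWRWGATPKKMEPTKSIWYCPKFCMLPGGQGTHSRMKSDPKWTGWFANKCLLPVRSM
>G013_hom07
MLRLGTMKTNADGNTCPACYTRCVWLGELTDWTEVQYNWWSGCWVMKGAGCHSPNLVKRLHIMFERLEADYIISRAYTEDDKQEAYPKLIPITGSWWPKLHITELGLGNVSRPYVKSEPSDPTTIASVCLECFIGC
>G013_hom08
MLLDMRDRTAHCLDAGPWLLFILLSLKELLDKFFETHTPWSPCRLRKGAYCAPLNHVALLLNHWECLGDHTEMWRLGYEQDDQCSTGGLIPYGFEIDPSPPIMWLGAGQSSSRLAGWKPPLWVIEAAVCLMLFWDG
>G013_hom09
MYRLNTGAQYTHLLTSPQRQNEYHLLPENIMSKLMRYTGFGGSVVFKNAECISLQVCAQLPIGIECSRWNLRYSRVGYPVDRQMDTPKFIDFAVSIYPSNLYFRLGRGNGSLLKNKSKPRLPRTIEHHCLLCFTDC
>G013_hom10
YLFIEWGKTLVCQCMWPQVASILNPRGEETDSTLVLYWLGSMCRYRFIAGCWMCKCVARLRGMLECLRKILEFSEQGYMQDRIEAIGALTPRTGSTWPITHNKVLYYGQTMRPLTKNWPKVCVEITHVWLILFFDI
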