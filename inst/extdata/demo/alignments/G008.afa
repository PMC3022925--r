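>G008_S288c
MSGLLYGRPALVNRDRRLSGLNAQRPCLRLCFVVYMQLSLPTERKYLHATGAYSNDTRCLPERTNLGMRCCLSCLAGDRLDINPPGERLQSIAEWVSIALRSNCVCTRVTKWVIPVENARQRGP
>G008_hom01
MFPCMVGYVPLRNIYRRLSKLNAQSPWLHECFVVYNQWCNCTLRVYQHETQAYSNQTRFKPERTKMKMRYVVSGPALDKGDINPHGERLQSIFEIVSTSLRMDWVCTRVTGVVIPIENAELPGP
>G008_hom02
CSGCTPNSIKLVDMPRRLKCNRGQRGCLRLHKVHYDQFVLERIMLYLFMTPAEQIDGLHLPARTNLTSRPCSSFLDTERYDICVPGMELQSFAKFLQIGYEWICHDSVVPDAYIKLHNGRQRGK
>G008_hom03
PVPHIIVWPFNVVRDRRLPGLNKSKKVIRLRVMGVMEGSFPTERKCLGAETALSPDTEKCPHRTWLFMFQALYCWWFRRNNIFFPPDHNQYIEEIFSIMPHGNCVWTRCFKIVWPVYNARQPGN
>G008_hom04
MPQLIYGRNGPTNVVGRLSALMPARAHARLKSRGFDHRSLPEERPYLHYTWFYWHDTRCPDTEMNGGMNDVLSCEAGDRRDINCPAVRHQGIAWMVTIRSRSNCVCQRVTKWVIPYEHATQKGP
>G008_hom05
SYCLLYEWPALPNDDRVWSGQNCQRLKLPLVSVVYMGLSWPTECQKASATGPYNNDGRWLPSVHKMGMNCQDSNLAGERLGPNPPGEVEQSCMEWLPIATRHGCVCTRVTWKIQPIECAIQLPP
>G008_hom06
MSGLLYGRPIFVNYFQRLYGFNSPFPYLRLQFVVGECLSVRKEKFYLKKTGYFNTDARCLGETTNLKERCCLSTQVRDHMDIAWCMGRLAWINEWVSAALRSQCVCTRVCTWFMVRLNDRFRIH
>G008_hom07
MSGCETGRPAQPNGDRWNSGLNASRMCLWLSMGVYMQTTLPIERCILPRTWETSARWRERPIMALLYEDCLLLCLYGFGLHDNPPGTKLCSLFFFCSANLRMVWVCSGFTKRPYYYEYAKQRGP
>G008_hom08
ASCLLCCRCHAVRRDRRDSHLETWRPNLVFCRVVYMQLSLPELRPYLHANGASSTDTWSLCEEMNDGMRDCTSFLYGDRLDINPMAERLQAIAEAMSTALRGMCVISRFTRCGIPVMNACKRGK
>G008_hom09
MSDLLKISPGAVMRDRRLIKLKWRQPAEALCDVCIGVTGLPGQLWMLACETAHSYNSRCNPLATGLGMRCCLMQRAQDFKDMNKKWSRYRSNKELVCKYIRSACVCTGVTVWCHPRELCSQRGP
>G008_hom10
MSSLLPGRDPMMTRDRRSSPLLQQRPHLRLYEVPYWRLDWNTGRWYLHPTGAYSLDFYCSPELTDSGMGCCRHLKDGDPLHKTPHSLRQWTPYELEHYRLRQCQVCIRLPQVILPVEVELFMCR
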