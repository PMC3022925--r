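>G020_S288c
MSRCGCAKRLANLGGAKGTKETPRRADSDLFSVVQTFSLRSPWGGGGSRWDEPRRLSSATGASCLCQTSVASLRADFCVSNQLRVKRHQWMLTPTFRGLSWAFLLEDLTPIYQAYPRKTKPCCVCYFRGRVA
>G020_hom01
WARGGCRKTFCNLLDKKGIEETPEGADSLRDFVVNTFNMVSNWQGGGAHYDMPHQLSSSFGASCLHSTSPASLIKKFCWQNQGRVKQVDCMNCPTERFLSFAFLQNHLTPTQQARPRVQKPCCVCYWRGRES
>G020_hom02
PDRDGAAKRLANCSHNKCTFKSPRMADSDLFSMQQFFFLRNEKTGKGQRDLLMVRRKSPTREDKVCGTEHASDFADFPFIVQLAVPMTKWRSKPNNAGLSWAQLLKDKTIISDAQPRKTKPAIVVYQRGGSF
>G020_hom03
MDNCDEEGCLPNDGMWSCLKETQRRRGGALISVVQFMDAVSPDGHGGSMWDEPERAQSAPLSSQRCQTHVARDPAQFNQSNVLRKTRSQWMPNLTFRGSSIWFLMEFICYLTHAYWRKTDPCCMCNFRGRES
>G020_hom04
MSRAGCFCSLACLGGMRGLHATPNKTGYDLEQVRKIQNQRSPWWNPASRDGQSDLLSSATGNSRVGEMKDAALRHAFKFECQMVGKRHGDMATPIFRGLSYCELLHDCTPIYQAKNNYTLPRCPCNNLGAVR
>G020_hom05
MARRAYWHRLHRLGNADGTKEGPRRAQTDLFSVGPNFSQRSIWDTFHSRFLEPRMCSSMTGFAFLCQCSQASLRADFCWLNKLVVDAHLYMLQPNNRGAICDFLQMVLMQWCQDYPRYTTPCCHGYFCGRVC
>G020_hom06
PSGWGVISTVASLGGAKEVKNPPNRQDDMNFAVETVFNWHQEAAGGGSRWDEPRRLSSQTRPGCDCQTPVYSLCAEFLVSNHLMVLARKKMLTPTCVGARWLCLHELLFPIYNAFARKTAPHNCDYLPDPAP
>G020_hom07
SSHWGEQSGMAYPAKRKIESETPNRKMSALLEFVQYVSYISPGGGRGADVSPAHAFARWTHAGHSVGIWVISSAAHQVVIVQLRVRCHIWWLIPFERALAYKFLLEYKTQILPPVFRKTQIMCVCYFFPRRN
>G020_hom08
KFRCACHMMLINLGGWHGQKETPRADHSCLFSVEPTFRLESPIGPGSSRFDEAFLTSSPGVESCLCQTSVPSHNADTCVSIQSTVKRFRHSETHTPDMVMMAFLAEDLAMPQQAYDRKMRLSCNAYFFGRYG
>G020_hom09
CRRHDCTKRLKNNGGVRGWKLTTRCADCWPFSVVQSAESHTPWGGGPNEWQQPCKTSSAYGASCLTQQKVTSLITDFDVSNQYRIIRINCMPTPTWNGLSSAWYLRDVGPYHQARPRMTKPSVDCWERGRGL
>G020_hom10
NSWAGCAKSLAILGLSKVTMCTPHRVRDDYFSVVQTFMPRSPWWGYMWRHCEPRGLSSATEYVTLCQRPVAKARQQFCVYWHLRASWHQWMISPIILGVSWAFALQDLHPAYIAYPWKDPICWDYYLIVDVA
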