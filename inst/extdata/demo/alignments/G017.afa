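>G017_S288c
MQLRTWTVLVATASLPAFFLCRVVVYLRAPGACTNVTTPCILRCAERIDPFWLSILPAISGPTVPFPIKLRLPVTLVAIPNGRTQLVVRVSRASTIAIHTYYCEYGNA
>G017_hom01
MFPCLVTYVNARAIYPAFFICRVVRYWRIEGACTNMTWCNCLKCVEPIEPQWLSIQPAEKGPTVKMIIKYVVPFNLKALGNGRTHLVVRVSRFSIIATSTYMEWYGNA
>G017_hom02
CQLCSPMRIIATEMPPAFLCNQFVVGLRAPHKCHNDTFVCESHNLERFMPPWEQKLGMGSGATVPFTSKPRSPETCSEIYNGCVQLLERVSFAIFMRIFYEVKEHCTV
>G017_hom03
PVPHIIVWLENTVSLPAFQLCRIRKKVIAPRVNGWVEGPGILRCACRGDETWMSPLPFKCGGTVWFFIFQALYVWWFRIMMGFFQPDHMVYRESIFAIMNHGCEYWNA
>G017_hom04
MPQRIWTVPFPVAVVGAFFACMNAVAGAAPKSSGFDHQPCIERCPERIYPWELWHLPAINDTEMPHPIPCVLPVELVAIRNGRCQATVHVGRAWMITIRRYYCEYGRA
>G017_hom05
SYCRTWEWLVAPADLPVWFLQRAVVLIRQPVSCTNVGTPWILRDQLASDPFNLNILGAWSGSVHKMPIPLPDPMTLVEIPFPRTQLVTEVSCMSTMQIHSYHHEYGNA
>G017_hom06
MQLRTWTVLHGTAYERAFYLGRRPFYYRAPQACTGECTPVRKRLGERKKPFYFNTLAAISHPSVPFIEKLRLPSPVQAHLNGAWCMFVRAWRNSTIAAHTYYQEYGNA
>G017_hom07
MQLCETTVLVQPAGLPWNFLCRVRVMLRWPSMHTNVTSTCIIRCDKRPRPWDVSARWADQGHMALFYEDLKLLVTYVFGPGDRTQLSKRCSKFEFCAANTYMVWYGTH
>G017_hom08
AQCRTCCVCGCTRSLPADFGCESWVYNRVFGRCTNVTTPCIEKCPERIDNFWTSTLPWSSCPEMPDPIKCRTPETYVAIPNGRTMAVVRVARASANATHTYGNEYITA
>G017_hom09
MQDRTKHRLFCTNSLPAFKICKWQQYAECPGECCIGVSGCIGPMWNRAAETWHSYNTAIMGKAVGFPIKLRLMPQLPAFKNMRKKWRVYQSMKSLIDKYIYYAEYGNH
>G017_hom10
MQSRTPTVDNMMTSLPASFPCLPVVYGRAPYFCPNWQTDWPLFCWERIPPFWLSMLFYIRGPLVDSPIGLRRHKKCVAQPGKTTHSKVPWTNYSLEIYRTYQDQYGIA
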