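>G014_S288c
MALQNSHRAEITTSDQVWMLELMRAPWFNLTSGSLQGFRPSALQLIRTDGITLITGPKLLEMLLRWMKTNLRPMYGRFTYTYKERSYSVVIYTAEANPAQEIRVTTFDSVPRHPSVIVLRITCRHYMYALPAHPTWV
>G014_hom01
MCLQNSRRHYITTLMKVKMCCQMFIPVFPSTATSFDLFRISKWNLPCMDFWRLITQCKCNYPMVMWDLTQDRQVTGRFFYTYPERHYSVMIWYDENSPQNEIKVTTADQVPNHPAEIGLRIDCMHYVYGLSNHHTMH
>G014_hom02
MALQYSHRQEACNSDQMWMGKSHNAYQRNATDGSLFYFHPLRLQEIETLWIMMESYNDNLFMVCIRHKDNLAPPPCWFTYNYHDRSFEEGIIGNEANPISHPMVYTFNWRLRHASMNREQIGYRHSHYALPAQSQRD
>G014_hom03
MANINSHRRMITTSDKQWNHEMQRWNWNNCTKDDGQGQVAMAWSAILQTRQTWITSPKEKEITLEFMKNGLRMHVPFDHYTYAPRYYPTNIVTAVAAPAKEIKVTTFIEVPILNSVMYVKQPNDHYMIALPALPTWV
>G014_hom04
RNIQNRSRIEIVTPQPILALCAYQIPQFNLECGELTGFLESWLLSKMTRNATISHGCIDLEMILRWQQTCASPKYVCFTYTDEECAYANVYQTAEANGTSKIRWASWDDVPRHPEFVMGAITCNHYMQAAPNHWTWV
>G014_hom05
SALQFSTRASITTHMVFHMLRELGACWENLTSLSGVGFRPLFLQLIRTDITLHITCYKKLGRTLMQMKTNGRPCYGCFTYTTKERLPSHVIYTVDANPCEGVWCTIGHSVPSHWCCIVLLITKRHYMHHQPAAANGE
>G014_hom06
MALWWYVPAEITTQQQFWMDEEMRINWQAHCRKSLLHDRESAEQLLETPNMHFIEAPKLYEMLWRVMKLRLLPLYCKCKYRYQLPVYSIVGFKTEMYPALYIRVTTFQMQRHHPSVHPLYTCWCHAYEAHRSHPMWN
>G014_hom07
MAFQNQGPAEIVSRDCVLMKELKRITWFNLTSGSHQGFRPSPLQLIRRDGDTLNLSPKYLIMWERWKKTQMCPSYTRFSCDYKPRAYVVVAYTAQACDAQYIRPTTIMTVPRRPMVPTMRTTCIHYHYFLPRTPTWV
>G014_hom08
PAGYASHRAEITTMPQVWMAEWMREPFFNLIENKQKHKRPSAMQLLRVDTMTCLEMIKLLLMEVRGMFSLLRFNNGQFTYNYKERSDSCVIETPRVCPKQQQCLNTYDSSPDHCEIIDLRQLCRFYMIANHEHPEAV
>G014_hom09
MCLQNSHQATITTPEQVYHLRLHQTPVYNLTSGLLQGFRASAMMLCERDGLCLYIGYKLLEKTHRPMKTNLRPMYGRQTNTNTCRSWEVRIYASEANPFQEARVTQFNTPPKVPFIIWLRHCCRHYMYALWAHNTEV
>G014_hom10
GHIGNVHRALITQSFQNWKIDAARSPRPNPTAGSLYGFRPSQDALIRTDAILLITMRKQQPKDLKCRGTDLRTMYTCFMYTYKENSYSVVKYFVEEIPGNYCKLSDADFVPDKPSRYVERDARRDKFYMCPAHPTWV
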