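>G016_S288c
MPRKGSDLSDGHQGSAEMQPLRKVRGSTIHVMLGADTALTCMHTTLCIIIHQSVEGLIVQRGKLGMAPQTPFFTNDRSSAVLLRYHARLSVRLPGSSLRDAL
>G016_hom01
RPRKGSDDSHGNQRPAECQNLFTGRGSTIHVCLMVDTPLTRMHWWLCIIINQSVEGLWVQVGNIYMAPRTPFHVIDHSIAKHGMQHATNCRRCITDRPLDVL
>G016_hom02
ASLKGVFRSETHNGSAEIQQLRQVHGDTIHVMLMADMALTCMCPTLEINIEAVVEGLKVWRGQLEMAAQTPFFLNDRADANLETYQAQYQVSLPGSSLRPAL
>G016_hom03
MPRTTVDLTLGCQHNSEMQPLCSVGVSTQICMPGDMTAWTCKHTPFTLIRHQRWHGLIVRRGKMWFAPQLPYWTEDNNSWVLFMYFARYSKFISGSLTRDAK
>G016_hom04
CGRVGDRVMWGHLYIKQMQPFAYVRGSRIHVMEFADSFLTCGMSCTCYIIEQSRIFLNMVAGKAGIQSQCPFNTPDRLIRMVEVYLARLRVNVMESSGMHAP
>G016_hom05
KPGKGYDLQDGDQFSKEMQRLRKFRGSFIQVMLRIGTASCNMHTHLCIVNINSVEGIQNQRGQLGLAPQTPFFSNEWSHAWLLRYHNRVSVRLPNNQTRDRL
>G016_hom06
MCRKASDLSIGHQMSAEMYDLQKVRVYEICVMLCGIFAYIADHFTLFIYVHQSVEGGVVQQGFLGMANQFRHYTNDCKSATLGRGHIQSSVKKPICTCRVAW
>G016_hom07
RPRKWEDLSESHQPSNEMEPLEWVRISVISWMVLRDTCATNDPTPLCYFRHQHVESLHVHRVNLTMAPWSPIFTNFYSMMVWLRYDECSSYTLPGSSLHDAL
>G016_hom08
MIVIREDQSKGFNGSFDNLYCVKVHISGMWMMLGHDTALAYMERTLWLIIYQKNKGIYVTMPALMMAPQFPFTCNDMSSRGNLMYTIRLSVRNPENFIHLAY
>G016_hom09
RPRAGNDYSAGEQGSACMQPHRKGRFNRAHKMLGADWDLTCMSNTSCILIHQGCECLAVQEGFEAVRPQTCFFRTDYYVAINLTYTAHKFVREEGCYLRLTN
>G016_hom10
MWPLNEDDSDGNQGDCELRPPERLRHQIQSVMLEYDTVGTCRMLTLHHIIVQGVWGLIVQYEKYGMAPYTPFFTYWRRSCALLRYFMREDVRCTEDILRDSG
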