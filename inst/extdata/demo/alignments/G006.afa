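>G006_S288c
MRYRGRWPSYRWFFEPGAKFVHLWVSACDVIKTPGENHGVNPLAPASLERCSVACTFVFGVGGCVNCVARASKDGTFPQLVRIGFGSPYPVHYESRLQYGSCRGEYCSQPTKPSPTRRLKMQNFA
>G006_hom01
MARRGLCPIKRWFWEPGAVSYKLWTKKFWVCWVPEEMHYVNQWIGASLEMVSFACRFSFGVLQCWSQVARARDDLLIPQWSRIWCPGPYAVFLESRPQVGSYRDEYESQPTIPSPTRKLKMQQFP
>G006_hom02
LNERVGNPSYRFIFEPTAKGVHLLGRLCHSRKTPNPLSDRCALAPARQIRKSLANEFVFVVGGCVKHKAIACTDHTDIWLERTGFVRPSPVIRRGCCRWSSCMGEYCSWPRDPHQMRWLGEQLGN
>G006_hom03
YSHDERDCYYQYFFEPGAWFVHLDVSAYDVIDTPGFAEVVNIFLPADLFRCSVLCTFLFYVGGNVKCVAGASPQRYQYQLVLPGFQPQSPVHRESRLRYGSHRGNYLKHPTKPSVMQRLGMQNFA
>G006_hom04
FRYIVVWQCLRHFLPNALKENFMQSSACDGIKAPGENHKQNPLAPASEEMKQVACFGPHGLGPMVNRQPTASTDGSQPVLISIGAGIPGKVKTIIRWEYHWMRIESYSQQTKANPSIRCKIQFKT
>G006_hom05
MQGRKRPIYKKWGAEFCAVREPCPFDWHRYIKTRGENHGVQRKVAASSFRQMVACEEVFNDHWYVCCVARFPKDGKIKQLVRNKFGSRYPKHYERQSGTYSCMENFCSQKTKPAPTRRLKMCNFS
>G006_hom06
MRDMIRWRSYRQFFHPGAKPSHRWAMAAIHDCYVGENERGAMNAPSSHVLCSVWATEWGIMQVCSDCEARLYKSQTSPHLNDGTWWSPYHVHHEKRGQLGLCEGWYLYHPTKQNPPQRWKGLNFA
>G006_hom07
CRKIGRIPKYRECAWHDAKFMHLWIVACDVDSPPEENQEVFPLAPASLCRVAEAITFSFCVGAAVRIHARALKMGKKPHLFRIGIGVPKWFWYEFRMQYWCARGEYIVQVFHPSPTRRLKMQYIA
>G006_hom08
HRYKWRWNGMRGDDEPEWKTVHNWVMAITWYKTPQWPRGVTPQAPASLWRPRVACFRVFHVDRAVPYTKRWSVDMTFPMPQRIGKLSKVRPHVEVRSRDGQCRGKDCSQPCCPSPGLWLHNGNFA
>G006_hom09
MPNMMQIGLYRELCEPNGKFVQLWVFAMSVIKTPGTCHCLNELASNMLARCSGGNPPIIGCGGCVDCMNAHVTDARTHVGVRWMMGSPQHVHYELPLEYGFCAQNGCSQPLPAMMTGRHKMQLFL
>G006_hom10
MIERGAWRSYRWFQEEGATGAHLHVGACDVQKTPKEMHGSNERAPAWYEFAGSNATFNFFVMGCDNAVATASKDRTFPQANTIGMASFQLSHRESRLWHGSCSIEACSQVTQPHATRRVAIQNQA
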