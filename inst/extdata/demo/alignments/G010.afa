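>G010_S288c
MFETGRRVVTFSVRCFRRMVKSHYPITMACELFAILPRYHPHGNYLKPRFCSHPWLALYAGEFVFTTENPGWSPRPAVKPKRSPTVTGSLVGCKNVNSSPANPAHEQNPS
>G010_hom01
NGEHGRGVVTFSRRCWRQMSKSPYKINMAYALVACLVVDHPHGNWLKMYIWSHPWLPMWAFFIVQTTEHPGEINEPAYCWKRIPTRTPSAEGVKNSNHSPMNVALEQNFS
>G010_hom02
WSCTQRHQQSKPEYQWRRPRKSLYMCAMDCERRAIAYRYIPPQNYNQPMFCSKPWLMLYSYFPVFHTFRPMWTLSPKPKPKLLICIRWGYAKYKNVYSSDANRPNKQNSS
>G010_hom03
FFYDYQNAVTHSQNCFHQMMLSHYPIGMNITLFKILPYHHSHENFVGEPFQSHKHLASKIPEFQKTTEQWHWLPRPASKTCRNPTVSGCLVGWPNVNSSPANPATEMNPS
>G010_hom04
MFMCKRRNPTFSRWHFRRNGHSHYPITMRCHWAYILIRMHAGFNYLCPHACSHWWWAGQAMSAVEHTENWKWIRRRFWIPKRTDTYFDSDVHMKNVYSCTAFPAHEQNPI
>G010_hom05
CMEGMGHVVTLPQFVFRRWWISHYPITHCEEPKAEGYDDVHRMNDLPMRNCSHWCLPLYAGEFVFCIKNWGWTDRPAYTPDRSPQVNCSLKAFKNVNSSEINPADEQRPG
>G010_hom06
GFLCKRRVTTYCVNCWVWNANYYDRIQDKGETFDILVRTEPYPNYFKVRHCLHPWHDDYAPKFQFIPFWTGWSSTSCEMPDRSPKWSNSEVHDCNYLPDYARAWHERTPN
>G010_hom07
MFEDSGEVKTNRLRFFRRMPESHHERTMCMELFAWLPCYNMGKNYLDPRFFQDVWSALYASSKVFTWWMPGVSAREAVLPLRPHTVFFANDAEVNVNSETANPAHEMWDE
>G010_hom08
MDETGRRVMFWSVECSRLCVISHTPCPMARYLHFDLSRCHPHLNRQNPQFQKSKWMAQYSGCFVFWTGNPGISPDPMVKPERSVPVTSSLVDVKMVKGSEAHYAHEQRHS
>G010_hom09
PSEQGSRMVSCSVRSFRRMVGSHDPITMAEDMFALLDRYHPGGQYLKIRFMDPPCLILYQEIVPFTFPFPRWLPKPMMLPKLGQTITKSEVGSKHSKSSCKINSIWGKPS
>G010_hom10
CDWKGMEVVTNGVMRFYREVKSNWPHIREYEIIPSDPKEDPIYNKLKPRYCSHKWLAQRVPIFVFTTENRPWDWRPAHMCTVLPTCTGILVGCPSVNSSGAWPAKIQNDI
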