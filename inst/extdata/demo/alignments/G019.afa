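>G019_S288c
MLARGARLETPLTSRGDRPMSRLAFRKCSNKKGRWASGPAVYRPTSTLGVDIILARDIRMRELAQQNAFSVSPCHWCIPTSRREDLSSSVRILLQARIRLAEIAVNDLSLTRRYAHTYFGPSPANKRGQGKPDRNKAAIILRTGVLLN
>G019_hom01
AAFRGRRLITFLTSVFKRPMSYLASRKCSNLPGTHAPEPPDPPLRATQGVDIPCARDNRMRELAQGMAFSVEACHYGITTRRFMDNWKSRNIFWVARERSAEIPMNVDSLCIIYAVVYFCPSQAAKRGQGHGTPNHSACTQGHYVCRM
>G019_hom02
SLELLQLRVWPLTCPWIRPMAMNGFMKNYNKTIRRASQPCVPRPTALLQWHIIHAQYIYMRTAPQQNAYSVYPCHNLHPTSNITDLMSSVEGWLMAKNRDAEGHFCPPDDKHRGYHTYFKLMPINIRGQGKRDRAKATIILATWYWAN
>G019_hom03
MLDRVARLETPSTSRPDRPMSEHQFTCCLVNKGPWASGPATDSPTSTLQVDIALFADIGCRELAQMYAFMVSPYIWMDPSPRRADLSSSVPIKRQQCIVEVALAVKDASLTRRYAHTYDGGSAAPKTWMQKFARNKAAIMTSYIKLLS
>G019_hom04
GLARAARLELALTSRQDCPNSHLAFRKCYVRQTRAGNHPAVYMPTQTEGVTIMDSWSISMWENEQQYEGPMSPHTLCIPTSQSTDTSHSVWILEYARIRLQCCAFDHEYQCRFYTCTCPDGHPINNRGQGAPDRAKALTTLRFGHSLN
>G019_hom05
MYAIYARTSIPYDSRGTRFMSRLAFRKMSDLKGRRLSGPAVCMPTSTYGEDDINAFENHMITTDQSMSHCNPPCHDTRPTYRREKLSLSVRITLQSNIRLYEIAHNWKALTKSGVRIYIGPSVANKNGRRGPTRKNDCIITRTQRKKN
>G019_hom06
MLLGKAALRTPLTWQGDQPHSRLAFRKISNKKKREHLGEFAYRPMSMLDSDIILANHHRMPWTAIANLFPCSRLEWNGPTSRRFMLSCSVPNWLQAWGALDIYAVNDQSLYPNHAHTYWATSAWDKREDPKPDLIKNMDPGYTWGLLN
>G019_hom07
WCAIGARGEMPSTSPVILPMSRLLDMECPNKRGCWQHSPAQYGPTSTRSVDIIMNRDIQMHELPNQNGFSVVEQHWCFHTHWKDPVSSSVRINDQHWISLGAPDVIWESLMRRKAHYYFGPSRANKRGYGKMDRIKMAIKLFTGVMDN
>G019_hom08
HLAVQACMETQLIYGGFRDMSRGAARDCSNQSVNPSIMPAWRRYTSTTGIDIFLARDITIESLWRQNAACECTCRWCIHHSRFEDLWLSIRILQQYQMGLCEVRYVSLMWTRRWIRTTLGCSCMAQAGQGDKDPKKWANICVCHVLLY
>G019_hom09
MLALYNDYEHYLSCRGCEPYGRLWKRMCSCSKGRWMSPYCNTMWIRTLWIDIVLQFDIERRELAQKNAFSPSPCHRCLPGSRNEDLRPWVGILWQARIPMAEIACPDLSTEDRYAHTYSWPSPCTKWKCGKPVMLKAHIHLRTGVPAT
>G019_hom10
MWAKGFRKETPLTSRQTRRVSRLAFVQIFQLNGRWNFGPYIEPPTSILGVDRMLASDIRVVCLYQVNAPSGSPCCWCQSTSHWSLLKSEMRILMQAISRLTEPAVVMLEKKERQQHYKFAWPWAQPRVGAKPDRANAATIVRDGWLLW
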