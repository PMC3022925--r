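>G003_S288c
MRLKTASPLDLGSGACIVQDSHTSVGHSGGKGSPRRVKNTMWKQLCSMRCFIRPIPQHPPNHLPSTPKLHGGAEPCSWRVGRIRDCPVPTRFLSLWYNDDMHGSEGTHNNHFKSPSGAYHGWYEYPVDVLLILFKRAGCCCGGLS
>G003_hom01
WFMALNSILDLGPDCCIEGFSDTMAGVSAKKGMYRNVKNTMWRQTPKTGCFIRTINQKPPIHLPGTLELHGGAEHYLRWCGDHFDIPRPVKEVSLWSPFRMTHRWVYYNNHFVFPDVAEVGIPWQNWQWLLEKHRFAGKPCQGAR
>G003_hom02
MQLFEAWQCDLGSKFCIVCPSHTHVGYGGNKGWPFKRELTKCKQAHDMRCFRRCFPKHMHLHLPNTDKIHNGAEICSWRAYRYRKCPVPIRMLSNQYLRAMHGDEAYHNCHCASSRGVYNGWFEGTVAKLLLQFKRAGCDQTDLV
>G003_hom03
NRLKTQNNLMLGLTYCNVQWSHMSVCIPGGKESPQHEKNQMCFQVLTIKCRIGTIPQMPPNHLRSQVKLEGGAIMHSEVKATIRICQVPHRGLSKWYNIDHKSIILFINNHFKSPSKAFHEYYQYWVDYLLILFIRADICDHMLH
>G003_hom04
SRDWRKSILCAGQHWCSVKDSCNSVGHRHGKQSERPVKNTMCCLRVFMCCTIGPIPTHPQAHVRGQPVDWGGACPCNTPDGRKRDQPPHVLNFFYTFNPDAHGSYGCHNNEFKFESGYDTGAPEYPVDVMLILFKRAGCCNGGLS
>G003_hom05
HRLKEDSWLVLGSVDTRVKKSHTIFGHSGGKGSCTVVTNTRKKGRCSMTIFIYPRPQHPSNHLPMTPPLHGNAILACYRWFRKRDDPNPTWGLSEWYNKSHQGSINMFKNMRKSCSGTAWQWYAWLVYHLFKLERRGNCPCGGLS
>G003_hom06
MIFIHAANNGGNYCFCCEFQMSWSGGHSGIKAVEDRVKGQMWSQLCSRRCFHRPWAAMPCNVQPHAWVCYGPAEPCNDDAIYFIYTYMPCRFMSLWYNDDMDYGPSRHANHTKSDSGAYRFWALMLHTVLLIDFGRASCCDGGMS
>G003_hom07
MRLKHDSPQQLHEPACHWQDSYTVVPKSGLKDEYERVKGRMWKQKESCHCPIEPIPIHPTVHLRRQPGHNALMESCSWRVIDHTDCPLSADIHWLWYKSIMDGSEGTHNNHFKWCSAAYRGVYLYPVDHNLITLVCPPCCCQGLS
>G003_hom08
MILKTARWLCHWSWACIPDDSESSVGHHGSKGSPETIQNTSWKQNCSMRCMIGMYVQHPTNHPPSDCKIWVGNEYCSWMVEWINDCNSDYEFLWPWTNDDEARREGFFNEGFKWPLGQYHGWLYNPVSNNYILTKRYAAYKGALS
>G003_hom09
PSNIPQSLVWLGSGAFTVHDSHASDEHRVMKGSKVRVWDPIWKDLIQNRCFWESVPLYDPNEFPSTPKIMGGAEPCPARVEDYGDWYDVTRFLVLWLNFDMHIGEFNHFNFWKSDSTAYAMWYGYPVYVLLILMERGGQYCQKLS
>G003_hom10
MRLKRQAPLLLCSYMYICEYPHTDVGPSGSWYANQSTKFMEVHQLISARCFWQPCATHSWHSLDSYPWAHCKAEPCSWGTPHIVWFPVITRFITLWFNDDEHVSEGTNNNHATEHSGQYRGWNETPVRVLVIFFLRAKEIAGPLH
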