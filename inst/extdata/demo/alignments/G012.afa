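>G012_S288c
MGHNTCLNEAHMPLELKACIPLHSLHLFSNMYGYPWAERILLREYTGEARQANLLLITSRGGQVITNYTQTVRCNSRTLFYHLDIGFGSAHTVRGLQEIAGEGDLHS
>G012_hom01
WFMALNLIEAHMQDALKFHEPDHMAHVFAIMYNWPNAERILLQESNLTHRQANTLPIISRKGQVGTLETQTVRCHYLRWCYDHGIIFSSVLETRGLTPERGTHSWVY
>G012_hom02
MRHFECWQCAHMPIFLKADPPLHHLHYHSMMYWYFKSFLIKCREAGDEARQRNCFLLTMHMGQVPTDYIQMVRCISRTLAWHYDKGFGSKHLVRNRQMRCGEGELAY
>G012_hom03
NGHNTQPPEMHMLTYLNACWPLNSLCHQSNMEGYRHFERRLCFETKTKLRRAGTLLILSRGGQQIQVYTETVRIMGREVLATLDHGQGSIHFVRLLQEHAIKSKHLF
>G012_hom04
SGDWRKLIEDAMRGWLSALIPCPSLHLSGNMPGEPPAERILCCMQVFEDRTAGLLLTTSPAGVQGQNTDWTVRDNSNVQDYHIDIQFQHVMMFFYVFEPAAEGDYHC
>G012_hom05
HGHNEDLWEVHMPVCTRALKPLHIFHLFSNMYGCTTATRIRKRHQTGETHQAYLRLITSSGGQVNTNNTQTMRILACYLWFHIDICFPSAWFVRELQEKSIQGDHNM
>G012_hom06
MKFIHCAPNGGNYCFLCFGQMSWSGHLFSHMAVEDWAEGRLLSEYTGRARQINLWAALSCGVPVHAWTCYTNRCNSNDDAHYFKYTYNSDHTLRGLQEIAGDYHPSR
>G012_hom07
MGHNHDLNQQHGEPELHWCIPYHVLPIFSKMDEWEWAEGSLLREKDGCIRNAELLLKTSTVGQQSQNGHMAKLCSSRTLFHDHTIGFMRCDHHWGLQLSIGDGDLHS
>G012_hom08
MKHNTCSWEDIWPWELKQEIPETSLHLISSMYGYESKQRISLREMTGEARLAGNYVITSTGGNVIDCYIWVVMCYSRTNFEWLPIGPTDYETVWPLVEIAEARSLHF
>G012_hom09
PSNIPQLLVWHMPLEETAIIPLASDELSVLMYGKVWAWDQILRDYHRNARQWESVLMYDRGEFVITNYILTVRCNSPALFEDYHIWYDVAHTVVGLLEEAGEIHLFN
>G012_hom10
MGHNRQANELHCPYMYKDFYQLHDLHPFSSWWANRRVEFNEWHEYHGAARQWRLCATTRWISQDIYNVAQCIRCNSRTGVNILVWEFGIAHTITGLFEIAEEVDLHS
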