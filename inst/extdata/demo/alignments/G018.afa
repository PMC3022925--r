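>G018_S288c
MCMGLPSWITYCAYILIQCVYLRHRRAMVMYGQLRTAGTLLNFEPCGAICYDRFIFLVPIVLSEHTTTKVKSCRLYKDVVA
>G018_hom01
SMQFSPSWVVQCAVYAWQYVYLTTRRAMYIYGPLHTHPMLWGFEWCNAIKYDRFRFMVPDWWSYHNYPKTKSISLEKWVYY
>G018_hom02
MRMGLSQDVTYCAYFLQKQVVCWLMWAYNMQRWLRGAETDHRFTVCEDICMAEFQFDVPIVLAYHTFMSQCQQRLYKDKVD
>G018_hom03
MCHHYPTRLTEPDYILRQCVYPRDMFANVMHGWLIIMGYWLPFEPHGAENRDRIIFLVVIILTCPWWHVVLQCRLNSQAVW
>G018_hom04
LKMAGCQAITLCAYELIQCVCLRHVMAEVWTFQMKMHGTLPFEEPCGAIEYNRFYQNVPIVTSDHVNTTVKHCDLLVDTVT
>G018_hom05
MCMWDAKWVTYCAYELIDCDFLQHRQAMHAYLQLRPAGILFNQLPAGAIDYDRCAFLVPVQLTAHDHTTWVSLRLYKDESN
>G018_hom06
MPMKCPCWIPICYCQLWVALSSRIRDVMVMKTQLSTEQTVHNCEPMGSIGYCWFMKLIPIYLSGHEMTKFASCRCTADVTA
>G018_hom07
SGMRWPSKITVCCSKLDTLVYWIHRMKSMMWGQARVALEKLNFIGYGPACILSFFFMPPIVWTNTGTDCGFSDPLMKDKEF
>G018_hom08
IAMQEPKKKCYCAAICQACEYLNHTNTMNIYGQLNTAGQHLLFEPCGMGCPHRFIYRCGIVLSEHETTKSKHCRLGSSSVA
>G018_hom09
NCAGLPFESTYWRISEEQCVYGRVGRAVALDISLRTLGCYLTREPCWSNCYDRQIISVHGCLHDHIMQLVKSCRLYPDCLA
>G018_hom10
SYMGLPFDIKYYITIFIYTVYLRYYQAFALPSFFLMGITLVNFAPRGAECYDCIAFHNMKVLAECTPQFLVCCTEHYMKRP
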