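>G002_S288c
MAKSKSSLAESYNAKRYQLSGVPDPIRSKKLTLNLQLPKWQTALLGVRSYSVSPIRVLVMEANPPSGSSPDLLMVPVGTI
>G002_hom01
WCKFKSQLTGAYNLDIYQIEGVPFGIRSLRDFLNPQLNMTQNAQLGVAHWSLSHRRVLRFEANPPGSSSQDLLIIIVGWR
>G002_hom02
PEKCKASLAESYCSGMYCLFKSPDMIRSKKLTNRLFLFKWNELTLKVQSDKKMVIQKLNMREDIVSHSEHDLDFVPVPFK
>G002_hom03
MEPSDDDGDENYDAMWRCMSGVQDPRFGAKHTLNLFMDATQTELGGVRMYSVSEIAQLVQLSNQRSGSHPDSDQVQVNQI
>G002_hom04
MAKAKSECSESCNAKLQQMHAVPPKTFYKKEQLSKIQNQWQTAWNPARSDFPRDMRVLVMENNRVFEMKDDALMGAVKFE
>G002_hom05
MCKQAYWHAEGQNANRDQLSGGPDPIPTKKLTLGQNLPQWQIADTFGRSFKVSPNCVLLMEFAEPSGCSRDLLMVPVGWM
>G002_hom06
PAGWKVHSTVSRNAKRYEVSNPPPPQRDMNLALETVLNWHRECALGVRSYSVSPIRVLPMRPGPDSGSPPYLLCVDVLTI
>G002_hom07
SAHWKDPSHMSWPCIQYHERGVPPPKLSAKKEFNLYVPYIQTHLLRVADVRNAHAFASWMHAGGSVHIWPILSAVGPVTK
>G002_hom08
KGKSASGMNEHYNAKWHQRSGVPDACGSCKLTLEQQLSKEQTKLPGRRSFSVAFMTVLNGVENPPSGSSPPLHPVPSGTI
>G002_hom09
CSKGDSTLAEIYMAKVQQWSLVTDCIRCWPLTLNLTAESHTTALLGNNEYPPSCLTVLVYEANPPTGQKPTLLISPVCTI
>G002_hom10
NAWAKSSLSESINALSYVLLCVPIPVQDKYLTLNLQLMPWQTAWLYLWSHCVSPGRVLVMFYVTPSGRPPDKAMPQVGTY
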