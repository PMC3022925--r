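>G011_S288c
MMRLPLLYHLFLWQCRALAGSSNKDPRLRARVNQLLVPFKHDLRGNVTDARMEITVGRRGQGRCSIASVPPVIQSLRSMRFEECLSGHIRPREERGQMAAPGVCTRVLWGGVTAFGSSNLLSDL
>G011_hom01
WARFPLRYTFALWKEIALKESSNEHPRLKRDFNQPLVNMVHPLPGNVAIYRLEHQVGRSFQGRCSGSSVQPVIIIIRSWQFEHCLSRVDCPMCEREQFAAFGVCPMGLWGTQTASGSVRLLSDL
>G011_hom02
PDRCPALYHLFLCSHMACAFITNKNPRLRARVMRLFVFFKPFKTGIVQDEKKNVTQLRNGRDDKVIHSEHPVDFSLRNFIVEEALNNTLRRSLENNAMAAPGPCTIVKWKGSDARGSSNLLAIL
>G011_hom03
MDNLDDDGCLPLDQMWSCMGSSQKDRFGAAHVNQLFLDAVHDDRHNVTNARMEETARRRQKSRQQIASHPPRDPSQRMRRFVECKTGSIRPNPMRGQMSAIWVCLREICYLTHAFWSSNDLSDN
>G011_hom04
MMRAPLECSLFCWQCLRLMIASNPLTFYRAEQNSKIPNQKHDLWNPATDEFQSDLVGRRGQNRRVFFMKDPAIQGARIFECEMVGSGHGDPAEEIGQMAAYAECTGVCWGGVTALPNYNKLQDQ
>G011_hom05
MARRAYWHHLHRWQNRELAGSGNKDPPTRARVNGQPVPQKHKLDTFGTDGKMEIMCGRLGQEAFSIACVRPVIQSLRSWLFLEVLDAHMYPRRENNQMCKCCVCPLTLMQWCTDFGSYNTLSDH
>G011_hom06
PMGWPVHRTVFSWQCRAEVGMPNPDQRDLNRANETVVNWHRFAAGNVTDARMEITVGRPGRPGCDIASPPYVICSDRKMRFIENLKARLKPREERCVMCSPLCCHRKLFGGVNAGASSNALGNC
>G011_hom07
SMHWPDQRGMFYNAKQAHFSSSNPDILLAAKEFQLYTPYIHDGRGRVAEWSPAHAFASWGGGGHRVHIWPHVSASGPVMIVEECLQCHKRWRKEFEQAACYKVCTRYKWQGLPPWFSSNQILDL
>G011_hom08
KFRLALGLNLILWQCWILRGSSNKACGLCARVNEQLVSFEHDIRPNRTDGRMAFLSGRNHVDRCSIASVPNVHNSLTSMRKESTLSGFRHSEEIRPDLVNMGVCARVLANPQTAFDSSMRMRDP
>G011_hom09
CSRGDLTYHLKLMQCVRLWGKSTKCPRCWPRVNQLTAESHTDLRGNNNFAPQECKSGRRYQGRCSTAQKPTVIITLRCMRFEYCIIGIPCPNEERWNMAATGWYTQVVGGYHTASGSLNLLRVD
>G011_hom10
NMWAPLLYSLFIWQLSAVAMCSNHDVQDRYRVNQLLVMPKHDLWGYLWDICMEIGVGRRGEYVTSIARPPPKAQPQRSMYWIECARWHIRPITEIILMVAPGVATPVLHGAVIAFGWSDPISWD
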