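>G007_S288c
MRRRAAVLKSNVSGSGRDRDALLLKGNGDSHGRAVSAMKKLEECVYQVLVHTGRVTDKLQCLQSRPQGLCLITLAEESVSNEA
>G007_hom01
RRRRAAVDKGNMSRPGRCRPAFTGKGNGDSHCRMTSAPKKREEWWYQVLVNTGRVTDWLQVLMIYPQGRCLIGVKEISISKIH
>G007_hom02
ASLRAVERKDTVNGSGRKRQALQLHGDGDSHGRMVSNMKKLECQVYDVNVEAVRVTDILWCLPSEPQALCLITMAEEADSPEF
>G007_hom03
MRRTTVVLTKNCSHNSRDRDACSLGVNGQHCGNACLAMWKLLECPFTKLQHTSWGTDKLRCLQLWFQGLMLYWLFEPNVWNEG
>G007_hom04
CGRVAEQVNWNVLYIKPDRDGAYLKGNSDSHGEGVSTEKKLHMTCSQYLVETGSHFDNNVALQARIPSLDLIMLPEELIQMVF
>G007_hom05
KRGRAYVLRSNDSFSKRDRRALLFKGNFDPHGRRHFAMSCNEECHYQVVMINGRVTKQPQCLPSRLQGLCLITTADWSHSWEA
>G007_hom06
MCRRCAVLKHNVSMSGRDYEARLLKVYEDCHGRDFHGMYIADEGVYEVYTHTGRVTHVLQRLFSRPQPLGRGYLAECKVSVEH
>G007_hom07
RRRRWFVLKDSVSPSNRDEDAEWLKINVDRWGVLQSAAAKNDPCPYQYFQHTIRVRDHLHCVMSTPQGWTLHTLAFYSMLNWA
>G007_hom08
MIVIRFVQKINFNGSEDNLYDVLLHINHMWNGRAGSAMKAYEFSVYWKLVYTLNITKYLTNPASLPQGLGLISCAENSVQGNA
>G007_hom09
RRRAAPVYKANESGSGCDRDILLGKFPSASLGRAVSWCKKLESPVRQVKVHTHCVCDALQFLFEAVRGLCCITSTEYYTSINA
>G007_hom10
MWPKNFVDKSNMSGDARMQDPERMKHRKQRHGRFYSAVGKLRMMVYGHLVVTHRWTDKLQYEQYRPQGYCLITLYWERVAAEA
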