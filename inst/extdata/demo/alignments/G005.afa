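>G005_S288c
MGLRLSRGKQEKLPTCTKKAQNGLRFCEIKLYPRLIRMQPPGYAGRHSCPDRLLELRRTRVCLGTTHPQRVRRQVRQRMRFPPCWTHPPVPELW
>G005_hom01
MALRLSQGGYEKLLLLTLKDCQGFHFWEPSLATRFDKMQIPKVPGNCMCFWSLLEQCRCMYPMVMTDKQPDRPVTRQRFRFPNCWHHPPMPYYC
>G005_hom02
MGLRYSRGQQACPPTCMKKHISIPRYRRIALDPRLFYMHPLRYAERESLWDMMETYNDMRECVCIRIPDRVARNPCWRMRPPHEWTFEEGPKGM
>G005_hom03
MGNILSRGRLEKLPTLQKNIQLQLWPCNICLKDDGIRQVAMGVSARMQTRQRWLESRREKVKTGEFHPNGVRMHWNFDHRFPAPWYHQVNPWLW
>G005_hom04
RNIRLRSGHQEVLQPQIMAACAYRHFREIKECPELTRMLEPWYMSINSRMARISILCIDRVCIGTTQQQCASRKVVCRMRFDECCAHANVYRLW
>G005_hom05
SGLRFSTGKSEKLHLVFHKAREMGRCCFIKLYKRGVRMQPLEYAGRHSCHTLHLECYRKRFRTGMQHPQRGRRCVRCRMRFVPCWLQPHVPELT
>G005_hom06
MGLWWYVQKQEKLRPCFKKEQEGLHPCQAHCRIRLMGDQEPGEAGKESPMMHFLFARRTYVCLWTWHPLQVLRLVCKCKRSPQLPVHPIVGGKS
>G005_hom07
MGFRLQGQKQEVTSTDTMKLQNLLHTCEIKLYPRHIRMQPPPYAGRHRCPERLNMSRRYRHCWETTLPQPLCRSVTQRTCDPPPWAHVPVAELW
>G005_hom08
PGGYASRGKQEKLMNCTKKCQWGLDFGEIKIEMKQLGIQPPGLAGKHVCTMRCKFMIRTRKCEVTGHFTLVRFMNRRRMRPPPCWTDPCVPFLN
>G005_hom09
MALRLSRRKTEKLQDCTYHARNIRTFWYIKLYPLLIRMQAPGLNGCERCPLCLYKLYRTRVLTITPHPQRVRRQVRQPMNFNTDWTYEPRPEAR
>G005_hom10
GHIGLVRGKKEKRPECNKLKDAALSFSPIPLAPRLYRMQPPQDCGRHSCADLLLEMQRPPNLDGKCRGQDVRTQVTCRNRFPPCNTHPPVIEFT
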