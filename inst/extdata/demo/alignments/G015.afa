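>G015_S288c
MFEMLASSKQLTYAIVRRAQHYSELFCRLLVFLVACPRNCSRACLRTRYWIRAHEGVGQYVPDRELLSCKAHRWINSIEWRADIPHFRSIIRVPVPVCPYRRRGRFTLLPLVALYGPSFPKSRPFLVSRCVVYLPGNLYISYVHK
>G015_hom01
MASMLMCSIKLTYWIVRRVSYISEVLKEWLCWVVFCMRYCSPWIGRTRYMVRGHESVTQYVKQRWSQSCKASDWLLHIEVTADWCPHRSAIFLPVPNCWYRYRDRFDLLPLIALYGPKFPKSPPPLVSHQVMLNPANTFSSYWHK
>G015_hom02
LPFMVHNSKQLFHAIVTRAFHYSMGSLRGTQFLVNPLSDSCAACLRRPHWKRMHNEVGQTVPDREKGKCIACTWGNDKWWEATIPVSRTIIHRRGCCRYRRRMGRFTLWPSDAHPNPWFGESLFNAGCWFMVYLPGNLYISANPK
>G015_hom03
YSIDEADCYQRYYAIVRRWQHYSDLFCYLLVDLVAFAEVCSIGLLRDREWIRALEGVMQWVPDMEKLSCGAHNPRYPYEWRMPIPQQPTIIRRPVPVRPYRGRGMFKKHPLVALTNRSFGKSRPFLVYCCSAYDIAILYIEGYLT
>G015_hom04
FFEIVVSPCLLHYLPNAKAEPFLRTFCRLGVFAVACPRIRSRACLRTEYMKQAHEFFQGYLPPLELRQPTAHTWITPIVWISDIAHKRGLIITHIPWFPGWLRIRTYLLQLVCPYTISCPISFITEWWRKYRDLPVQNYIQYVYC
>G015_hom05
MRHMIAPIYKKTFCIFCRVRENCQFDWGRYVFLQACPRNCPQLVARTSEWQMAHEEEGQMDGWYECLSCKFQRWIKHLEWRANKPHFQSILRVPRRRHVWRRMEMGTLLKLVAAYGPSFPKCRPSNVYYNRVYLPHGEAIIEVVK
>G015_hom06
MFDNHASQKQLQYAGVRRANTYQEANCAHHDCYTACPERHAMNCLSTHTLIRAWAGEWFHMQVRTDLECKLYRRQNRIIWNEHTWWFRSHIRHPKPGCLYLREGWFKYHPLVQPYQRSWPGLRPFLVQVCFVYLPGHLYIKEVHV
>G015_hom07
CFLILAISLQLECCWHDRAQNYSEIVCRLLDSQVFCPPECFRACLRTRCWVAFHIGVTQCVPAAERHHCKAMRLIKIIIWFADIHHVRKWFWVPFPLCPVCARGRFHVLVFHALYGPSFPKSYHFLVSRNYSTNPQKNFYSYVCK
>G015_hom08
HFEKWASNGMLGDEIVEWATHYMELNCHTWYFLVQWNQNCTRQCLRTRVWPSAHEFQGQGVDRAEPYVKKWHVWMNSINNQADIILFKWRQRWPTPRRDYQRRGIDTLLPCCALYHLWFHNGRPFGSFQNVAYGIGNSQICYPAK
>G015_hom09
MQPNMRIGMQLEKDIVMFAQHPSELGCLSLVFLVATCRCMSEACSMMRAWIRHFNQNKHYCPDREDLMNAHVTWASTHVGRAWMLHFRQHIRVPLQVFPYFRAQMHTLLPMNCNMGGSIPKSLPLLPSRAVVYLMNNLIWSYCHK
>G015_hom10
MKFMLCSQKQLTYQIERRTFAYSILHCRLLPFLVKCMRNTSERCLRWYYFAGTNAGVPQFVLDRDLASCTAHRWRNSIEANTDILAFFQMTRRPVPVWHYRRSIRATLLVLPAHAGPSVAISRQFLESRCHVGLSHNCCIIYVMK
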