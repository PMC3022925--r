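>G009_S288c
MAPQLTKFSQVVSVYSSMVRLLKRSHRLKFCESPVTNKCQYRAIDTHSMSESIPVTVQLLQWGYWDLTSVPMLQQSGSSSWNWYQCQDSRAVTLIKCG
>G009_hom01
SMQFSTKFVVQVSWWAWMYRLLTTSHRLYKCEPPHTGPNQVGAIWTNSMIESIPQTLQLDWVGWWPYPSTPMHSQEGWSYYNWCNWQDSILHTGEACG
>G009_hom02
MRPQLRRDVQVVSVFSPKPRWCWKMWRYPFRRWPVGNECDHQATVTECMSNAEPPTDQLLQWAWWDFMRQCRQQQSGSKSCVWYQCYDQRAVIKDKCG
>G009_hom03
MAHGYTTSKQENCVYSQMVRLPKDMFRNKFIEWPIILKYWYNAIDGHSEMSSIHVTVQVLIWTCNWWHVVKRLQQNSPASVWPYQIVDYRAKSLIKCL
>G009_hom04
LKPAGCRASQLVSVESSMVRCLKRVNREKWVGSLKMGKCQNFFIDTHSMDEMIPYPMQLLQSGDWVPTTVPHLDQLVSVSSNDQQCPDSRYVPRIFCG
>G009_hom05
MAPWDALFVQVVSVESSDVDFLRRSRRLHACLSPVPNKKQFRQLDAHSMCESICATVQLVRWTAWEHTTWVMKQQSGSETMFWIQMQDSRAAVLIQTE
>G009_hom06
MPPICTCFSPIVYCPSWVALTSKHSDVLKFLTSPRTDQCVHRDIDLHRMFECWPLIVILLYWGFWFNTSFAMLQCVASSVWMHVQNFDSFAVTLVWCP
>G009_hom07
SGPRWTKLSQWVASISDTKRLWIRSNISNFYESAVVNLFKYRAHHYHNASKKSPFTLPLLQVTMSHLDCGFMCPQMGSKEENWGMSYDYWSEALIKCY
>G009_hom08
ICPPETLLICVVSAYCPAVELLPRTPTLPKCESPNTNKRHYLAIDTHLGSQGIPVYQCGLQWGYWFLTSSPHLQQGSRTSWNPYFCQDSNLVTLIKCG
>G009_hom09
NAAQLTFERQVWQIREEMVRLGKVGHRVAMEIRPVTKKDYYTRIDTWRNSESIQVHRQHGCWIDWKNQKVPMLQQSPSCLWYWIQCWDSVADNEIKAV
>G009_hom10
SYPQLTFDSKVYHTYFSYSRLLKYYRRFAMQSFFLMFHCQTRAADQHSESESCHATHNNIQWAYCDQQFLVCLTEHYLKRNSVNQCGWARPVTLPKND
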