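>G004_S288c
MQWEIKRCSRTRTMVPKSYWRIGGRSEVFATHYLLTSIVLTKISVIELLGCEARPARSRTETDPTDLSSTDVSGTRWYSEK
>G004_hom01
MCRCIYECTRTMTMVNSKYQRIGGRNIDFCTFHDAGLFRLAKINVIELFGCECCPTPSGTNVWWTDYKSNDRVICRRHSDK
>G004_hom02
LMWCIKVCSGTAYEYPECRWREWGRTEHIATHYLFLSIEPTKEVVIELAQCNANAARTRTEHFPTDVGSTDWSITTKPHEK
>G004_hom03
CVEGIKRCSMTITQTPKSYAFIQGRSIFFATHYLATSITLTKWSCIINIGCILRNGRCRTQNFIMKSWSKMVMHTWPHSFK
>G004_hom04
SQWYNTRELRPRICRKKSYWRWGQQLYYDGVHGALTFNNLFAIYNRMRQGCQAKSQPYYTFQKHTNLSSTTKTGHRWFHPK
>G004_hom05
TQWMIKLFHFTATMVPESQWRGYCRSEYFATHYHLEWRTMTVPDHHELMGCANRPHLSMTNKGTTVLSDTDDWDTRWYSEK
>G004_hom06
RQREWLDCHRPVTMVPWRSWSHGNRSEVFSFALCVTSSGLHAIFVIYLFDCENRPWESRCEAYPYVHSSSFMNGTRWYPLW
>G004_hom07
MQWEGKLCSMACGNVCKACYTRCVWSEVFATWSELPSPWLTKIWVNELLGCEANPARIRTITDFTRLESDYHHGTAYTSDK
>G004_hom08
MQLDNSDRSRHRTDAGKWLLFIGLSSKVFMTLYFESHVNLTPISLIELLYCAQRPIRSLTMMIWTDLGCHTVLWTLWYSEK
>G004_hom09
MYWEIKRAQYTGTMVPKSYQNEYGLSPVNKLHILNQSVFFGKSVVFENLECIARQVCSQTQTHPTDSSWMDQYGTRWYNVK
>G004_hom10
YQFKEWRCSKVRPCMWKSTARIGNRQEVEATHSLLTSIKGTMISYIGHLGCWNCKDRSRTEGDKTDLSITDVSGEQWYLEK
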