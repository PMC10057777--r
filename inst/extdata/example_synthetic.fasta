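>s01 Aromatase, cytochrome P450 19A1
GIGIVHRDSNIIHLWSRNCSMDFMCDRNALMCMLIYTSSELAAPVEELYDQGKIRMRLQM
SFFCQNIKAAPLTQEYHNCEQVQYAAVQSISAFRPTYGQTNNKLAKPCSYRFAWQVYALW
>s02 Aromatase (Fragment)
DDQRELFQFMHEELNFMLPRMKIGHMNKFEAAYRGIFSIETCFWACCIWFLRMDSHKRHW
ICARRTQTHQFVIEQNNYWMWTVCPGNIQTYGGFPKDHERGCKGFINVIE
>s03 Cytochrome P450 2F1
TTHTLRSDYGTDHNGDWRGTLCGVMVHDHAETFLTCGRWPPDYWWCQGWDIVQKNWDHFF
QIVCDVHKMRPSMDFFPPKTHWTGNFNAGQDVGPQICMKA
>s04 Putative steroid hydroxylase, isoform 2
EGKNNQKAVDPWVKFLDWSAAMHYMLIPGPHYRFQDAQIIVRVTGWFLPQHMGVECVVGV
MVYTLLHELKCNSNHWSQCSIRIRNRGRQCGGERN
>s05 Regulatory protein, uncharacterized
HDSKMQIPGMCKRRVYYNMCDENLWIMINNCWEKGMFHLKRCLSSNTVSLWIVVPAFFAF
WVRYRCGEWQHEAGYYAYVHYKCKQNMDPV
>s06 Probable cytochrome P450 oxidoreductase
SSCRMYWGFRLTMESSADVNAHYWVPNEMYQMPCDQTMTGCTAMVTKLPYFTKMILEWLT
KPMQVSIPCEPRSITCMKSQMNQPEVHS
>s07 Steroid monooxygenase
WMLTKDNCPTRVYAYWNTNGFKPGNAPAIKMVQFVVQENWFQAHKGDMPCEFSCLSSFFM
RSHAEWNQGRAHCLPQQQVVSFHHC
>s08 Flavin-containing monooxygenase
ILTLSYWFRCTVANYDMPGVCDSVWMWNSCHLHYFVIGIFSQRLNIVPYKGAQPRVQHNY
ANKRRTIDTNWTEKSRWFFD
>s09 Short-chain dehydrogenase
DSQWMTFITINIVGQAIYLESFQNHMLKPGGDCQRRHSVWTDRVTSAYKPIAGYVTSHVG
RWMYMTKTVPMCHKH
>s10 Aromatase, cytochrome P450 19A1 variant
GIGIEHRDSNIIHLWSRNCSMDFMCDRNALMCMLIYTSSELAAPVEELYDQGKIRMRLQM
SFFCQNIKAAPLEQEYHNCEQVQYAAVQSISAFRPTYGQTNNKLAKPCSYRFAWQVYALW
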