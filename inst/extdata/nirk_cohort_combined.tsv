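phylum	n	pct_combined
Acidobacteria	1	0
Actinobacteria	28	64.3
Alphaproteobacteria	82	78.0
Bacteroidetes	21	66.7
Betaproteobacteria	39	74.4
Verrucomicrobia	2	100
Chloroflexi	5	40
Deltaproteobacteria	2	50
Euryarcheaota	13	7.7
Firmicutes	27	55.6
Gammaproteobacteria	23	73.9
Gemmatimonadetes	1	0
Nitrospirae	2	0
Planctomycetes	1	100
Spirochaetae	2	100
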