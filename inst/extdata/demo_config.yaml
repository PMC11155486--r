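# demo synthetic-genome configuration: a small, fast instance of the
# packaged study conditions (see ?simConfig for every key and default)
seed: 1
nChromosomes: 2
chromLength: 60000
nGenes: 40
operonFraction: 0.2
tsGeneFraction: 0.6
ts5utrFraction: 0.5
tagDepthPerGene: 200
guAuBias: 1.5
decoyPeaks: 6
decoyClusters: 3
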